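# Readers and writers for the pipeline's interchange formats.
#
# Genotypes travel as a HapMap-dialect TSV (rs, alleles, chrom, pos, then one
# dosage column per line; dosage = count of the second-listed allele, 0/1/2,
# NA for missing). Gene models are GFF3 (1-based inclusive) and known-QTL
# intervals BED (0-based half-open, converted on import); both go through
# rtracklayer. Pathway sets are GMT via fgsea. Every writer drops a sidecar
# JSON with the generating seed and parameters next to the data file.

#' Write a sidecar JSON recording seed and parameters
#'
#' @param data_path path of the data file the sidecar describes; the sidecar
#'   is written at `<data_path>.json`.
#' @param seed integer seed used to generate the data (or `NA`).
#' @param params named list of generation/processing parameters.
#' @return The sidecar path, invisibly.
#' @export
write_sidecar <- function(data_path, seed = NA, params = list()) {
  side <- paste0(data_path, ".json")
  jsonlite::write_json(list(file = basename(data_path), seed = seed,
                            params = params),
                       side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(side)
}

#' Write genotypes as HapMap-dialect TSV
#'
#' @param geno a [geno_matrix()].
#' @param path output path.
#' @param seed,params recorded in the sidecar JSON.
#' @return `path`, invisibly.
#' @export
write_genotypes_hapmap <- function(geno, path, seed = NA, params = list()) {
  alleles <- if (!is.null(geno$info$alleles)) geno$info$alleles else
    rep("A/G", nrow(geno$info))
  df <- data.frame(rs = geno$info$snp_id, alleles = alleles,
                   chrom = geno$info$chrom, pos = geno$info$pos,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(t(geno$dosages), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sidecar(path, seed, params)
  invisible(path)
}

#' Read genotypes from HapMap-dialect TSV
#'
#' @param path file written by [write_genotypes_hapmap()].
#' @return A [geno_matrix()].
#' @export
read_genotypes_hapmap <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 5 || !all(c("rs", "alleles", "chrom", "pos") %in% names(df)[1:4])) {
    stop_param("not a HapMap-dialect genotype file: ", path)
  }
  dos <- t(as.matrix(df[, -(1:4), drop = FALSE]))
  colnames(dos) <- df$rs
  geno_matrix(dos, data.frame(snp_id = df$rs, chrom = df$chrom, pos = df$pos,
                              alleles = df$alleles, stringsAsFactors = FALSE))
}

#' Read genotypes from a VCF v4.2 file
#'
#' Converts diploid GT fields to alternate-allele dosages (0/1/2). Requires
#' the vcfR package.
#'
#' @param path VCF path (plain or bgzipped).
#' @return A [geno_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_param("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", g), "/"),
                  function(a) sum(a != "0" & a != "."), integer(1L)))
  }
  dos <- t(apply(gt, 2L, count_alt))
  colnames(dos) <- rownames(gt)
  fix <- vcfR::getFIX(v)
  geno_matrix(dos, data.frame(snp_id = rownames(gt), chrom = fix[, "CHROM"],
                              pos = as.integer(fix[, "POS"]),
                              stringsAsFactors = FALSE))
}

#' Write a feature table as TSV
#'
#' Header: feature_id, mz, rt_min, mode, then one column per line.
#' @param ft a [feature_table()].
#' @param path output path.
#' @param seed,params recorded in the sidecar JSON.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, seed = NA, params = list()) {
  df <- data.frame(feature_id = ft$meta$feature_id, mz = ft$meta$mz,
                   rt_min = ft$meta$rt, mode = ft$meta$mode,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(ft$intensities, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sidecar(path, seed, c(params, list(condition = ft$condition)))
  invisible(path)
}

#' Read a feature table from TSV
#'
#' @param path file written by [write_feature_table()].
#' @param condition condition label; if `NULL`, taken from the sidecar JSON.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, condition = NULL) {
  if (is.null(condition)) {
    side <- paste0(path, ".json")
    if (file.exists(side)) {
      condition <- jsonlite::read_json(side)$params$condition
    }
    if (is.null(condition)) stop_param("condition not given and no sidecar found")
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- data.frame(feature_id = df$feature_id, mz = df$mz, rt = df$rt_min,
                     mode = df$mode, stringsAsFactors = FALSE)
  ints <- as.matrix(df[, -(1:4), drop = FALSE])
  rownames(ints) <- meta$feature_id
  feature_table(meta, ints, condition)
}

#' Write a metabolite matrix as TSV plus a group-map JSON
#'
#' @param mm a [metab_matrix()].
#' @param path output TSV path; the group map goes to `<path>.groups.json`.
#' @param seed,params recorded in the sidecar JSON.
#' @return `path`, invisibly.
#' @export
write_metab_matrix <- function(mm, path, seed = NA, params = list()) {
  df <- data.frame(line = rownames(mm$values), check.names = FALSE)
  df <- cbind(df, as.data.frame(mm$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(mm$group_map, paste0(path, ".groups.json"))
  write_sidecar(path, seed, c(params, list(condition = mm$condition,
                                           log_transformed = mm$log_transformed)))
  invisible(path)
}

#' Read a metabolite matrix from TSV
#'
#' @param path file written by [write_metab_matrix()].
#' @param condition condition label; if `NULL`, taken from the sidecar JSON.
#' @return A [metab_matrix()].
#' @export
read_metab_matrix <- function(path, condition = NULL) {
  log_transformed <- FALSE
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    sj <- jsonlite::read_json(side)
    if (is.null(condition)) condition <- sj$params$condition
    if (!is.null(sj$params$log_transformed)) {
      log_transformed <- isTRUE(sj$params$log_transformed)
    }
  }
  if (is.null(condition)) stop_param("condition not given and no sidecar found")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df$line
  gm_path <- paste0(path, ".groups.json")
  gm <- if (file.exists(gm_path)) {
    lapply(jsonlite::read_json(gm_path), function(x) unlist(x, use.names = FALSE))
  } else NULL
  metab_matrix(vals, condition, group_map = gm, log_transformed = log_transformed)
}

#' Write a long-format phenotype table as TSV
#'
#' Columns: line, environment, replicate, trait, value.
#' @param pheno data.frame in long format.
#' @param path output path.
#' @param seed,params recorded in the sidecar JSON.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(pheno, path, seed = NA, params = list()) {
  stopifnot(all(c("line", "environment", "replicate", "trait", "value") %in%
                  names(pheno)))
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sidecar(path, seed, params)
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' @param path file written by [write_phenotype()].
#' @return A data.frame with columns line, environment, replicate, trait, value.
#' @export
read_phenotype <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand` (1-based inclusive coordinates).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = if (!is.null(genes$strand)) genes$strand else "*")
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$Name <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `gene`-typed records (all records when no type column is present).
#' @param path GFF3 path.
#' @return data.frame with columns gene_id, chrom, start, end, strand.
#' @export
read_gene_models <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_param("malformed GFF3 '", path, "': ",
                                                conditionMessage(e)))
  if (!is.null(gr$type)) {
    keep <- gr[as.character(gr$type) == "gene"]
    if (length(keep)) gr <- keep
  }
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else
    if (!is.null(gr$Name)) as.character(gr$Name) else
      paste0("gene", seq_along(gr))
  data.frame(gene_id = id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read known-QTL intervals from BED
#'
#' BED is 0-based half-open; rtracklayer converts to 1-based closed on import.
#' @param path BED3+ path.
#' @return data.frame with columns chrom, start, end (1-based closed).
#' @export
read_known_qtl <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read pathway sets from a GMT file
#'
#' @param path GMT path (one named gene set per line).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
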