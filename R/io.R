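# Plain-text input/output for the standard interchange formats of the
# pipeline: GWAS-SSF-like summary statistics, genotype TSV/VCF, square
# coexpression matrices, PGS weight files and BED intervals.

#' Write and read summary statistics as tab-separated text
#'
#' Columns follow the GWAS-SSF-like layout used throughout the package:
#' `id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `info`,
#' `beta`, `se`, `p`, `n`.
#'
#' @param stats Summary statistics tibble.
#' @param path File path.
#' @return `write_sumstats()` returns `path` invisibly; `read_sumstats()`
#'   returns a tibble.
#' @export
write_sumstats <- function(stats, path) {
  readr::write_tsv(tibble::as_tibble(stats), path)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = readr::col_character()))
}

#' Write a genotype matrix as VCF or TSV
#'
#' The VCF output stores dosages in a `DS` FORMAT field (VCFv4.2,
#' uncompressed text); the TSV output is variant-major with one sample per
#' column. Per-variant EAF and INFO are carried in the VCF INFO column.
#'
#' @param G A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  v <- G$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"ALT allele frequency\">",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$samples$sample_id), collapse = "\t")
  ), con)
  D <- t(G$dosages)
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".", "PASS",
            sprintf("AF=%.6g;INFO=%.6g", v$eaf[i], v$info[i]), "DS",
            formatC(D[i, ], format = "g", digits = 6)), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a DS-format VCF back into a genotype matrix
#'
#' Reads uncompressed VCF text written by [write_genotypes_vcf()] (or any
#' VCF carrying a single `DS` FORMAT field).
#'
#' @param path VCF file path.
#' @return A [geno_matrix()] (sample covariates are not stored in VCF and
#'   come back as IDs only).
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  sample_ids <- cols[-(1:9)]
  body <- lines[-(1:hdr)]
  parts <- strsplit(body, "\t")
  m <- length(parts)
  info_field <- function(s, key) {
    as.numeric(sub(sprintf(".*%s=([^;]+).*", key), "\\1", s))
  }
  variants <- tibble::tibble(
    chrom = vapply(parts, `[[`, "", 1L),
    pos = as.integer(vapply(parts, `[[`, "", 2L)),
    id = vapply(parts, `[[`, "", 3L),
    ref = vapply(parts, `[[`, "", 4L),
    alt = vapply(parts, `[[`, "", 5L),
    eaf = vapply(parts, function(p) info_field(p[[8]], "AF"), double(1)),
    info = vapply(parts, function(p) info_field(p[[8]], "INFO"), double(1))
  )
  dos <- t(vapply(parts, function(p) as.numeric(p[-(1:9)]),
                  double(length(sample_ids))))
  dos <- matrix(as.numeric(dos), nrow = length(sample_ids), ncol = m,
                byrow = TRUE, dimnames = list(NULL, variants$id))
  geno_matrix(dos, variants, tibble::tibble(sample_id = sample_ids))
}

#' Write a gene network as a square correlation TSV
#'
#' @param network A [gene_network()].
#' @param path Output path; gene names in the first column and header.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  df <- tibble::as_tibble(network$correlation, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(gene = network$flags$gene), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a gene network from a square TSV or 3-column edge list
#'
#' A square file has genes as first column and header; an edge list has
#' columns `gene_a`, `gene_b`, `correlation` (missing pairs are 0). Core
#' flags can be supplied separately.
#'
#' @param path Input path.
#' @param core_genes Optional character vector of core gene names.
#' @return A [gene_network()].
#' @export
read_network_tsv <- function(path, core_genes = character(0)) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (all(c("gene_a", "gene_b", "correlation") %in% names(df))) {
    genes <- sort(unique(c(df$gene_a, df$gene_b)))
    R <- matrix(0, length(genes), length(genes),
                dimnames = list(genes, genes))
    ia <- match(df$gene_a, genes); ib <- match(df$gene_b, genes)
    R[cbind(ia, ib)] <- df$correlation
    R[cbind(ib, ia)] <- df$correlation
    diag(R) <- 1
  } else {
    genes <- df[[1]]
    R <- as.matrix(df[-1])
    rownames(R) <- genes
  }
  gene_network(R, tibble::tibble(gene = genes, core = genes %in% core_genes))
}

#' Write a PGS weight file
#'
#' Three tab-separated columns: variant ID, effect allele, weight.
#'
#' @param model A `pgs_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pgs_weights <- function(model, path) {
  readr::write_tsv(tibble::as_tibble(model), path)
  invisible(path)
}

#' @rdname write_pgs_weights
#' @export
read_pgs_weights <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  class(out) <- c("pgs_model", class(out))
  out
}

#' Write clumped loci as BED intervals
#'
#' Each locus spans its member sentinels as a 0-based half-open interval;
#' the name column carries the tag variant.
#'
#' @param clumps Output of [ld_clump()].
#' @param positions Tibble `id`, `chrom`, `pos` giving sentinel positions.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(clumps, positions, path) {
  d <- dplyr::inner_join(tibble::as_tibble(clumps), tibble::as_tibble(positions),
                         by = "id")
  bed <- d |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     start = min(.data$pos) - 1L, end = max(.data$pos),
                     .groups = "drop") |>
    dplyr::select("chrom", "start", "end", name = "locus")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
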