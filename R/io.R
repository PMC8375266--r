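# Reading, writing and harmonizing GWAS / eQTL summary statistics.
# All formats are tab-delimited text with a header line.

.AMBIGUOUS <- c("A/T", "T/A", "C/G", "G/C")

.isAmbiguous <- function(a1, a2) paste(a1, a2, sep = "/") %in% .AMBIGUOUS

#' Read GWAS summary statistics
#'
#' Reads per-SNP trait association summary statistics from tab-delimited
#' text. The default dialect is the COJO ".ma" layout
#' (\code{SNP A1 A2 freq b se p N}), the de-facto standard for SMR-style
#' tools; \code{dialect = "tsv"} accepts any header naming the same
#' quantities via \code{columnMap}. Rows with non-numeric or invalid
#' effect/SE values are skipped (not fatal) and counted in the
#' \code{"nSkipped"} attribute; real summary files are dirty and a single
#' bad row should not abort an analysis.
#'
#' @param path file path.
#' @param dialect "ma" (default) or "tsv".
#' @param columnMap for dialect "tsv", a named character vector mapping
#'   standard names (snp_id, effect_allele, other_allele, eaf, beta_zy,
#'   se_zy, p_zy, n, and optionally chrom, pos) to the file's column names.
#' @return data.frame with columns snp_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta_zy, se_zy, p_zy, n; attribute
#'   \code{nSkipped} counts rejected rows.
#' @export
readGwas <- function(path, dialect = c("ma", "tsv"), columnMap = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (dialect == "ma") {
    need <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("format error: missing mandatory column(s): ",
           paste(miss, collapse = ", "))
    df <- data.frame(snp_id = as.character(raw$SNP),
                     chrom = if ("chr" %in% names(raw))
                       as.character(raw$chr) else NA_character_,
                     pos = if ("bp" %in% names(raw))
                       as.integer(raw$bp) else NA_integer_,
                     effect_allele = toupper(as.character(raw$A1)),
                     other_allele = toupper(as.character(raw$A2)),
                     eaf = suppressWarnings(as.numeric(raw$freq)),
                     beta_zy = suppressWarnings(as.numeric(raw$b)),
                     se_zy = suppressWarnings(as.numeric(raw$se)),
                     p_zy = suppressWarnings(as.numeric(raw$p)),
                     n = suppressWarnings(as.integer(raw$N)),
                     stringsAsFactors = FALSE)
  } else {
    if (is.null(columnMap))
      columnMap <- c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
                     effect_allele = "effect_allele",
                     other_allele = "other_allele", eaf = "eaf",
                     beta_zy = "beta_zy", se_zy = "se_zy", p_zy = "p_zy",
                     n = "n")
    need <- c("snp_id", "effect_allele", "other_allele", "beta_zy",
              "se_zy", "p_zy")
    miss <- need[!columnMap[need] %in% names(raw)]
    if (length(miss))
      stop("format error: missing mandatory column(s): ",
           paste(columnMap[miss], collapse = ", "))
    pick <- function(std, as = identity, default = NA) {
      cn <- columnMap[std]
      if (!is.na(cn) && cn %in% names(raw))
        suppressWarnings(as(raw[[cn]])) else rep(default, nrow(raw))
    }
    df <- data.frame(snp_id = pick("snp_id", as.character),
                     chrom = pick("chrom", as.character, NA_character_),
                     pos = pick("pos", as.integer, NA_integer_),
                     effect_allele = toupper(pick("effect_allele",
                                                  as.character)),
                     other_allele = toupper(pick("other_allele",
                                                 as.character)),
                     eaf = pick("eaf", as.numeric),
                     beta_zy = pick("beta_zy", as.numeric),
                     se_zy = pick("se_zy", as.numeric),
                     p_zy = pick("p_zy", as.numeric),
                     n = pick("n", as.integer),
                     stringsAsFactors = FALSE)
  }
  ok <- is.finite(df$beta_zy) & is.finite(df$se_zy) & df$se_zy > 0 &
    !is.na(df$p_zy) & df$p_zy > 0 & df$p_zy <= 1 &
    df$effect_allele != df$other_allele
  nSkipped <- sum(!ok)
  if (nSkipped)
    message(nSkipped, " GWAS row(s) failed validation and were skipped")
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "nSkipped") <- nSkipped
  df
}

#' Write GWAS summary statistics in COJO ".ma" layout
#'
#' @param gwas data.frame as returned by [readGwas()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGwas <- function(gwas, path) {
  out <- data.frame(SNP = gwas$snp_id, A1 = gwas$effect_allele,
                    A2 = gwas$other_allele, freq = gwas$eaf,
                    b = gwas$beta_zy, se = gwas$se_zy, p = gwas$p_zy,
                    N = gwas$n)
  if (!all(is.na(gwas$chrom))) out$chr <- gwas$chrom
  if (!all(is.na(gwas$pos))) out$bp <- gwas$pos
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read cis-eQTL summary statistics
#'
#' Tab-delimited with header columns \code{SNP gene A1 A2 b se p}. Each
#' (SNP, gene) pair must be unique; duplicates are an error because
#' instrument selection would be ambiguous.
#'
#' @param path file path.
#' @return data.frame with columns snp_id, gene_id, effect_allele,
#'   other_allele, beta_zx, se_zx, p_zx; attribute \code{nSkipped}.
#' @export
readEqtl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("SNP", "gene", "A1", "A2", "b", "se", "p")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("format error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  df <- data.frame(snp_id = as.character(raw$SNP),
                   gene_id = as.character(raw$gene),
                   effect_allele = toupper(as.character(raw$A1)),
                   other_allele = toupper(as.character(raw$A2)),
                   beta_zx = suppressWarnings(as.numeric(raw$b)),
                   se_zx = suppressWarnings(as.numeric(raw$se)),
                   p_zx = suppressWarnings(as.numeric(raw$p)),
                   stringsAsFactors = FALSE)
  key <- paste(df$snp_id, df$gene_id, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate (SNP, gene) pair(s): ",
         paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))],
               collapse = ", "))
  ok <- is.finite(df$beta_zx) & is.finite(df$se_zx) & df$se_zx > 0 &
    !is.na(df$p_zx) & df$p_zx > 0 & df$p_zx <= 1
  nSkipped <- sum(!ok)
  if (nSkipped)
    message(nSkipped, " eQTL row(s) failed validation and were skipped")
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "nSkipped") <- nSkipped
  df
}

#' Write cis-eQTL summary statistics
#'
#' @param eqtl data.frame as returned by [readEqtl()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEqtl <- function(eqtl, path) {
  out <- data.frame(SNP = eqtl$snp_id, gene = eqtl$gene_id,
                    A1 = eqtl$effect_allele, A2 = eqtl$other_allele,
                    b = eqtl$beta_zx, se = eqtl$se_zx, p = eqtl$p_zx)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a seed gene list
#'
#' One gene symbol per line; blank lines and lines starting with '#' are
#' ignored.
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Harmonize GWAS and eQTL effect alleles
#'
#' Restricts to SNPs present in both inputs and aligns the GWAS effect to
#' the eQTL effect allele, so that the two effects are comparable per
#' allele. When the GWAS effect allele equals the eQTL other allele (and
#' vice versa) the GWAS beta sign is flipped and \code{flipped = TRUE};
#' incompatible allele pairs are dropped with reason
#' \code{"allele_mismatch"}. Strand-ambiguous SNPs (A/T, C/G) cannot be
#' aligned without frequency information and are dropped by default
#' (two-sample MR safety).
#'
#' @param gwas data.frame from [readGwas()].
#' @param eqtl data.frame from [readEqtl()].
#' @param dropAmbiguous drop strand-ambiguous SNPs (default TRUE).
#' @return data.frame of harmonized pairs: snp_id, gene_id, beta_zy, se_zy,
#'   p_zy, n, beta_zx, se_zx, p_zx, flipped. Attributes: \code{nShared}
#'   (SNPs present in both inputs) and \code{exclusions} (named counts by
#'   reason code).
#' @export
harmonizeEffects <- function(gwas, eqtl, dropAmbiguous = TRUE) {
  shared <- intersect(gwas$snp_id, eqtl$snp_id)
  gw <- gwas[match(eqtl$snp_id, gwas$snp_id), , drop = FALSE]
  inBoth <- !is.na(gw$snp_id)
  ex <- c(not_shared = sum(!inBoth))
  eq <- eqtl[inBoth, , drop = FALSE]
  gw <- gw[inBoth, , drop = FALSE]

  same <- gw$effect_allele == eq$effect_allele &
    gw$other_allele == eq$other_allele
  swapped <- gw$effect_allele == eq$other_allele &
    gw$other_allele == eq$effect_allele
  ambiguous <- .isAmbiguous(eq$effect_allele, eq$other_allele)

  keep <- (same | swapped)
  ex["allele_mismatch"] <- sum(!keep)
  if (dropAmbiguous) {
    ex["strand_ambiguous"] <- sum(keep & ambiguous)
    keep <- keep & !ambiguous
  }
  out <- data.frame(snp_id = eq$snp_id[keep], gene_id = eq$gene_id[keep],
                    beta_zy = ifelse(swapped[keep], -gw$beta_zy[keep],
                                     gw$beta_zy[keep]),
                    se_zy = gw$se_zy[keep], p_zy = gw$p_zy[keep],
                    n = gw$n[keep], beta_zx = eq$beta_zx[keep],
                    se_zx = eq$se_zx[keep], p_zx = eq$p_zx[keep],
                    flipped = swapped[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "nShared") <- length(shared)
  attr(out, "exclusions") <- ex
  out
}
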