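# VCF import/export for genotype panels (GT-only, 1-based positions).

#' Write a genotype panel as a GT-only VCF
#'
#' Hard-call dosages are encoded as unphased genotypes (`0/0`, `0/1`,
#' `1/1`, `./.`); positions are 1-based as the format requires.
#'
#' @param panel A `genotype_panel`.
#' @param path Output file path (plain text, uncompressed).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  G <- panel$dosage
  body <- matrix("./.", nrow(v), length(panel$samples))
  for (g in 0:2) body[t(G) == g] <- gt_code[[as.character(g)]]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=isopqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t"))
  rows <- cbind(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE),
                v$variant_id, v$ref, v$alt, ".", "PASS", ".", "GT", body)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(rows, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a GT-only VCF into a genotype panel
#'
#' Parses the file with the vcfR package and converts unphased or phased
#' GT fields to ALT-allele dosages; missing genotypes become `NA`.
#'
#' @param path VCF file path.
#' @return A `genotype_panel`.
#' @export
read_panel_vcf <- function(path) {
  stop_if_not(requireNamespace("vcfR", quietly = TRUE),
              "the vcfR package is required to read VCF files")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  to_dosage <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x == "0/0"] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x == "1/1"] <- 2
    out
  }
  D <- apply(gt, 2, to_dosage)
  variants <- tibble(
    variant_id = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.numeric(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"])
  new_genotype_panel(t(D), variants, colnames(gt))
}
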