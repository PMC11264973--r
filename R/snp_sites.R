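#' Read candidate SNP sites from VCF or tabular input
#'
#' Loads the heterozygous-SNP candidate list the caller screens. Both VCF
#' (plain or bgzipped, via \pkg{vcfR}) and a 5-column TSV
#' (`chrom, pos, id, ref, alt`, 1-based positions, with or without a header
#' line) are accepted. Only biallelic single-nucleotide records are kept:
#' indels, multi-allelic records and records whose REF/ALT are not single
#' A/C/G/T bases are silently dropped.
#'
#' @param path Path to a `.vcf`, `.vcf.gz` or tab-separated file.
#' @return A tibble with columns `chrom`, `pos` (1-based integer), `id`,
#'   `ref`, `alt`, sorted by `(chrom, pos)` and deduplicated on
#'   `(chrom, pos, id)`.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("tx1\t50\trs1\tA\tG", "tx2\t61\trs2\tC\tT"), tsv)
#' read_snp_sites(tsv)
read_snp_sites <- function(path) {
  if (!file.exists(path)) {
    stop("SNP file not found: ", path, call. = FALSE)
  }
  is_vcf <- grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)
  sites <- if (is_vcf) read_snp_vcf(path) else read_snp_tsv(path)
  sites <- sites |>
    filter(
      .data$ref %in% c("A", "C", "G", "T"),
      .data$alt %in% c("A", "C", "G", "T"),
      .data$ref != .data$alt,
      !is.na(.data$pos), .data$pos >= 1
    ) |>
    distinct(.data$chrom, .data$pos, .data$id, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$pos)
  if (nrow(sites) == 0L) {
    stop("no usable biallelic SNV records in ", path, call. = FALSE)
  }
  sites
}

read_snp_vcf <- function(path) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in VCF ", path, call. = FALSE)
  tibble(
    chrom = as.character(fix$CHROM),
    pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), as.character(fix$ID)),
    ref = toupper(as.character(fix$REF)),
    alt = toupper(as.character(fix$ALT))
  )
}

read_snp_tsv <- function(path) {
  raw <- tryCatch(
    readr::read_tsv(path, col_names = FALSE, comment = "#",
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) stop("failed to parse SNP table ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(raw) < 5L) {
    stop("SNP table needs 5 columns (chrom, pos, id, ref, alt): ", path,
         call. = FALSE)
  }
  raw <- raw[, 1:5]
  names(raw) <- c("chrom", "pos", "id", "ref", "alt")
  # tolerate a header line
  if (nrow(raw) > 0L && is.na(suppressWarnings(as.integer(raw$pos[1])))) {
    raw <- raw[-1, , drop = FALSE]
  }
  if (nrow(raw) == 0L) stop("no records in SNP table ", path, call. = FALSE)
  tibble(
    chrom = raw$chrom,
    pos = suppressWarnings(as.integer(raw$pos)),
    id = raw$id,
    ref = toupper(raw$ref),
    alt = toupper(raw$alt)
  )
}
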