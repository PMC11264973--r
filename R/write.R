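# Output writers. Every file starts with comment lines recording the tool
# version, the full parameter set and the seed, so a run can be reproduced
# from its outputs alone; identical inputs and seed give byte-identical
# files.

output_header <- function(x) {
  c(
    paste0("# astructr ", as.character(packageVersion("astructr"))),
    paste0("# seed=", x$seed, " n_perm=", x$n_perm),
    paste0("# ", config_string(x$config))
  )
}

write_with_header <- function(df, path, header) {
  writeLines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write the per-SNP call table to TSV
#'
#' One row per retained SNP, preceded by `#` header lines with version,
#' parameters and seed.
#'
#' @param x An `astruct_result`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_calls <- function(x, path) {
  write_with_header(x$calls, path, output_header(x))
}

#' Write the per-base profile/StrucDiff table to TSV
#'
#' Long format: `snp_id`, `window_pos`, `es_ref`, `es_alt`, `strucdiff`,
#' `strucdiff_p`. Requires a run with `per_base = TRUE`.
#'
#' @inheritParams write_calls
#' @export
write_per_base <- function(x, path) {
  if (is.null(x$per_base)) {
    stop("no per-base track; rerun with per_base = TRUE", call. = FALSE)
  }
  write_with_header(x$per_base, path, output_header(x))
}

#' Export per-allele reactivity tracks as bedGraph
#'
#' Writes one bedGraph file per allele (`<prefix>.ref.bedGraph`,
#' `<prefix>.alt.bedGraph`) with the unit-interval structure scores of
#' every per-base-scored SNP window. Positions follow bedGraph convention
#' (0-based half-open).
#'
#' @param x An `astruct_result` with per-base output.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_bedgraph <- function(x, prefix) {
  if (is.null(x$per_base)) {
    stop("no per-base track; rerun with per_base = TRUE", call. = FALSE)
  }
  coords <- x$calls[, c("snp_id", "chrom", "window_start")]
  pb <- dplyr::left_join(x$per_base, coords, by = "snp_id")
  pos0 <- pb$window_start + pb$window_pos - 2L  # 0-based start
  paths <- character(0)
  for (allele in c("ref", "alt")) {
    val <- pb[[paste0("es_", allele)]]
    keep <- !is.na(val)
    df <- tibble(chrom = pb$chrom[keep], start = pos0[keep],
                 end = pos0[keep] + 1L, score = val[keep])
    path <- paste0(prefix, ".", allele, ".bedGraph")
    writeLines(sprintf("track type=bedGraph name=\"astructr ES (%s)\"",
                       allele), path)
    readr::write_tsv(df, path, append = TRUE, col_names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
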