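#' ROC benchmark of composite scores against a truth manifest
#'
#' Joins per-SNP calls to ground-truth ASRS labels and computes the
#' rank-based (Mann-Whitney) ROC AUC of the composite score, overall or per
#' coverage tier when a `tier` column is present in `calls`.
#'
#' @param calls Per-SNP call tibble (from [tidy.astruct_result()]) with at
#'   least `snp_id` and `astruct_score`, or an `astruct_result`.
#' @param truth Truth manifest tibble with `snp_id` and `is_asrs` (from
#'   [simulate_dataset()] or a `manifest.tsv` read back in).
#' @return Tibble of class `astruct_auc` with one row per tier
#'   (`tier`, `n_sites`, `n_asrs`, `n_non`, `auc`) and an `roc` attribute
#'   holding the ROC points (`tier`, `fpr`, `tpr`).
#' @export
#' @examples
#' calls <- tibble::tibble(snp_id = letters[1:4],
#'                         astruct_score = c(0.9, 0.8, 0.85, 0.7))
#' truth <- tibble::tibble(snp_id = letters[1:4],
#'                         is_asrs = c(TRUE, TRUE, FALSE, FALSE))
#' evaluate_auc(calls, truth)   # AUC 0.75
evaluate_auc <- function(calls, truth) {
  if (inherits(calls, "astruct_result")) calls <- calls$calls
  joined <- dplyr::inner_join(as_tibble(calls), as_tibble(truth),
                              by = "snp_id", suffix = c("", ".truth"))
  if (nrow(joined) == 0L) {
    stop("no calls could be joined to the truth manifest", call. = FALSE)
  }
  if (!"tier" %in% names(joined)) joined$tier <- NA_integer_
  tiers <- unique(joined$tier)
  roc_pts <- list()
  rows <- purrr::map(tiers, function(t) {
    d <- joined[is.na(t) & is.na(joined$tier) |
                  !is.na(joined$tier) & joined$tier %in% t, , drop = FALSE]
    if (length(unique(d$is_asrs)) < 2L) {
      stop("truth labels contain a single class; AUC is undefined",
           call. = FALSE)
    }
    r <- pROC::roc(response = d$is_asrs, predictor = d$astruct_score,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    roc_pts[[length(roc_pts) + 1L]] <<- tibble(
      tier = t,
      fpr = 1 - r$specificities,
      tpr = r$sensitivities
    )
    tibble(tier = t, n_sites = nrow(d), n_asrs = sum(d$is_asrs),
           n_non = sum(!d$is_asrs), auc = as.numeric(pROC::auc(r)))
  })
  structure(
    bind_rows(rows),
    roc = bind_rows(roc_pts),
    class = c("astruct_auc", class(tibble()))
  )
}
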