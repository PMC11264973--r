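# broom-style verbs and plotting for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-SNP call table of an ASRS run
#'
#' @param x An `astruct_result`.
#' @param ... Unused.
#' @return Tibble with one row per retained SNP: position and alleles,
#'   allele read counts, spanning (`r_d`) and total (`r_total`) window
#'   reads, window coordinates and length `n`, `pcc`, `esdc`, `p_value`,
#'   `astruct_score`, `group` and a BH-adjusted `p_adj` convenience column.
#' @export
tidy.astruct_result <- function(x, ...) {
  as_tibble(x$calls)
}

#' Run-level summary of an ASRS run
#'
#' @param x An `astruct_result`.
#' @param ... Unused.
#' @return One-row tibble with filter-stage counts, group totals and the
#'   permutation settings.
#' @export
glance.astruct_result <- function(x, ...) {
  grp <- table(factor(x$calls$group, levels = c("Low", "Medium", "High")))
  tibble(
    sites_seen = x$log[["sites_seen"]],
    heterozygous = x$log[["heterozygous"]],
    retained = x$log[["retained"]],
    called = x$log[["called"]],
    n_low = as.integer(grp[["Low"]]),
    n_medium = as.integer(grp[["Medium"]]),
    n_high = as.integer(grp[["High"]]),
    median_score = if (nrow(x$calls)) stats::median(x$calls$astruct_score)
    else NA_real_,
    n_perm = x$n_perm,
    seed = x$seed
  )
}

#' Score distribution plot for an ASRS run
#'
#' @param object An `astruct_result`.
#' @param ... Unused.
#' @return A ggplot: composite-score histogram coloured by group.
#' @export
autoplot.astruct_result <- function(object, ...) {
  calls <- object$calls
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$astruct_score, fill = .data$group)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::labs(x = "AStruct score", y = "SNPs", fill = "Group") +
    ggplot2::theme_minimal()
}

#' Per-allele reactivity profile plot for one SNP
#'
#' Requires a run with `per_base = TRUE`.
#'
#' @param x An `astruct_result` from [astruct_call()] with per-base output.
#' @param snp_id SNP identifier to plot.
#' @return A ggplot with both allele profiles and the StrucDiff track.
#' @export
plot_reactivity <- function(x, snp_id) {
  if (is.null(x$per_base)) {
    stop("run astruct_call() with per_base = TRUE to plot profiles",
         call. = FALSE)
  }
  pb <- x$per_base[x$per_base$snp_id == snp_id, , drop = FALSE]
  if (nrow(pb) == 0L) stop("no per-base track for ", snp_id, call. = FALSE)
  long <- bind_rows(
    tibble(window_pos = pb$window_pos, value = pb$es_ref, track = "ES (ref)"),
    tibble(window_pos = pb$window_pos, value = pb$es_alt, track = "ES (alt)"),
    tibble(window_pos = pb$window_pos, value = pb$strucdiff,
           track = "StrucDiff")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_pos, y = .data$value,
                                     colour = .data$track)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~ .data$track, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "window position", y = NULL, title = snp_id) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' ROC curve plot for a benchmark evaluation
#'
#' @param object An `astruct_auc` from [evaluate_auc()].
#' @param ... Unused.
#' @return A ggplot of the ROC curve(s), one per coverage tier.
#' @export
autoplot.astruct_auc <- function(object, ...) {
  pts <- attr(object, "roc")
  pts$tier <- factor(pts$tier)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$tier)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = "tier") +
    ggplot2::theme_minimal()
}
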