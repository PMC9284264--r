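# Heterosis indices, high-parent significance testing, and qPCR
# relative-expression arithmetic.

#' Mid-parent heterosis
#'
#' `MPH = 100 * (F1 - mean P) / mean P`, where `mean P` is the average of
#' the two parental means.
#'
#' @param f1_mean hybrid trait mean.
#' @param p1_mean,p2_mean parental trait means.
#' @return MPH in percent; vectorized.
#' @export
mph <- function(f1_mean, p1_mean, p2_mean) {
  mid <- (p1_mean + p2_mean) / 2
  if (any(mid == 0)) {
    stop_hybex("mid-parent mean is zero; MPH undefined", "undefined_index")
  }
  100 * (f1_mean - mid) / mid
}

#' Over-parent (better-parent) heterosis
#'
#' `OPH = 100 * (F1 - best P) / best P`, the best parent being the one with
#' the larger mean (or smaller, for traits where lower is better).
#'
#' @param f1_mean hybrid trait mean.
#' @param p1_mean,p2_mean parental trait means.
#' @param direction `"higher"` (default) or `"lower"`: which parent counts
#'   as best.
#' @return OPH in percent; vectorized.
#' @export
oph <- function(f1_mean, p1_mean, p2_mean,
                direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  best <- if (direction == "higher") pmax(p1_mean, p2_mean)
          else pmin(p1_mean, p2_mean)
  if (any(best == 0)) {
    stop_hybex("best-parent mean is zero; OPH undefined", "undefined_index")
  }
  100 * (f1_mean - best) / best
}

.stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
}

#' Two-sample test of the hybrid against the high parent
#'
#' Student's two-sided t-test (pooled variance by default) of per-plant
#' hybrid values against per-plant high-parent values, with the usual
#' significance stars (`**` for p below 0.01, `*` below 0.05).
#'
#' @param f1 numeric vector of hybrid plant values (at least 2).
#' @param hp numeric vector of high-parent plant values (at least 2).
#' @param welch use the Welch (unpooled) form instead of Student's.
#' @return list with `t_stat`, `p`, `stars`.
#' @export
high_parent_test <- function(f1, hp, welch = FALSE) {
  if (length(f1) < 2L || length(hp) < 2L) {
    stop_hybex("at least two values per group are required", "invalid_input")
  }
  if (stats::var(f1) == 0 && stats::var(hp) == 0) {
    if (mean(f1) == mean(hp)) {
      return(list(t_stat = 0, p = 1, stars = "ns"))
    }
    return(list(t_stat = sign(mean(f1) - mean(hp)) * Inf, p = 0, stars = "**"))
  }
  tt <- stats::t.test(f1, hp, var.equal = !welch)
  list(t_stat = unname(tt$statistic), p = tt$p.value, stars = .stars(tt$p.value))
}

#' Heterosis indices over a phenotype time course
#'
#' For every hybrid x trait x measurement day, computes MPH and OPH from
#' group means and tests the hybrid against the high parent. The day with
#' the largest OPH per hybrid and trait is flagged as the peak.
#'
#' @param records data frame with columns `material` (two parent labels and
#'   one or more hybrid labels), `trait`, `das` (days after sowing),
#'   `plant_id`, `value`.
#' @param parents character(2): the parental material labels (order:
#'   parent 1, parent 2).
#' @param hybrids character vector of hybrid material labels; default: all
#'   non-parent materials present.
#' @param direction passed to [oph()].
#' @param welch passed to [high_parent_test()].
#' @return data frame with one row per hybrid x trait x das: `mph`, `oph`,
#'   `t_stat`, `p_vs_hp`, `stars`, `peak` (logical).
#' @export
heterosis_timecourse <- function(records, parents = c("GH", "GB"),
                                 hybrids = NULL,
                                 direction = "higher", welch = FALSE) {
  needed <- c("material", "trait", "das", "plant_id", "value")
  if (!all(needed %in% names(records))) {
    stop_hybex(paste("phenotype table must have columns:",
                     paste(needed, collapse = ", ")), "invalid_input")
  }
  hybrids <- hybrids %||% setdiff(unique(records$material), parents)
  rows <- list()
  for (hy in hybrids) {
    for (tr in unique(records$trait)) {
      sub <- records[records$trait == tr, , drop = FALSE]
      for (d in sort(unique(sub$das))) {
        at <- sub[sub$das == d, , drop = FALSE]
        v <- function(m) at$value[at$material == m]
        p1 <- v(parents[1]); p2 <- v(parents[2]); f1 <- v(hy)
        if (length(p1) < 2L || length(p2) < 2L || length(f1) < 2L) {
          warning(sprintf("skipping %s/%s at das %s: missing group", hy, tr, d))
          next
        }
        hp_vals <- if (direction == "higher") {
          if (mean(p1) >= mean(p2)) p1 else p2
        } else {
          if (mean(p1) <= mean(p2)) p1 else p2
        }
        ht <- high_parent_test(f1, hp_vals, welch = welch)
        rows[[length(rows) + 1L]] <- data.frame(
          hybrid = hy, trait = tr, das = d,
          f1_mean = mean(f1), p1_mean = mean(p1), p2_mean = mean(p2),
          mph = mph(mean(f1), mean(p1), mean(p2)),
          oph = oph(mean(f1), mean(p1), mean(p2), direction = direction),
          t_stat = ht$t_stat, p_vs_hp = ht$p, stars = ht$stars,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    stop_hybex("no complete hybrid/trait/das combination found", "empty_input")
  }
  out <- do.call(rbind, rows)
  out$peak <- FALSE
  for (hy in unique(out$hybrid)) {
    for (tr in unique(out$trait)) {
      i <- which(out$hybrid == hy & out$trait == tr)
      if (length(i)) out$peak[i[which.max(out$oph[i])]] <- TRUE
    }
  }
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' `rel_expr = 2^-(((Ct_target - Ct_reference) - calibrator_delta_ct))`.
#' The calibrator sample itself yields 1.
#'
#' @param ct_target Ct of the target gene in the sample.
#' @param ct_reference Ct of the reference (housekeeping) gene in the same
#'   sample.
#' @param calibrator_delta_ct delta-Ct (target minus reference) of the
#'   calibrator sample.
#' @return relative expression (positive); vectorized.
#' @export
ddct <- function(ct_target, ct_reference, calibrator_delta_ct) {
  2^-((ct_target - ct_reference) - calibrator_delta_ct)
}
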