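# Paired-design comparisons and summary-table assembly.
#
# Every comparison in the analysis is paired within a preparation (the same
# trabecula measured at both sarcomere lengths, or before and after the
# force inhibitor), so the classical paired t-test on the within-pair
# differences is the workhorse.

#' Paired sample of matched measurements
#'
#' @param ids Unique preparation identifiers.
#' @param a,b Matched measurement vectors, same length and order as `ids`.
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(ids, a, b) {
  stopifnot(length(a) == length(b), length(ids) == length(a))
  if (length(a) < 2L) stop("paired sample needs n >= 2", call. = FALSE)
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  structure(list(ids = ids, a = as.numeric(a), b = as.numeric(b)),
            class = "paired_sample")
}

#' Two-tailed paired t-test
#'
#' Classical paired t on the differences `b - a`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, two-tailed p from Student's t with
#' `n - 1` degrees of freedom.  Zero-variance differences never raise: if
#' all differences are equal and non-zero the result carries
#' `degenerate = TRUE` with p at the machine floor; if `a == b` elementwise,
#' `t = 0`, `p = 1`.
#'
#' @param sample A [paired_sample()], or the first measurement vector if
#'   `b` is given.
#' @param b Optional second vector (then `sample` is taken as `a`).
#' @return List with `t_statistic`, `p_two_tailed`, `mean_diff`, `sem_diff`,
#'   `df`, `n`, `degenerate`.
#' @examples
#' paired_t(paired_sample(1:5, c(1, 2, 3, 4, 5), c(2, 2, 4, 5, 5)))
#' @export
paired_t <- function(sample, b = NULL) {
  if (!inherits(sample, "paired_sample")) {
    sample <- paired_sample(seq_along(sample), sample, b)
  }
  d <- sample$b - sample$a
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  sem <- sdd / sqrt(n)
  if (sdd == 0) {
    if (md == 0) {
      return(list(t_statistic = 0, p_two_tailed = 1, mean_diff = 0,
                  sem_diff = 0, df = n - 1L, n = n, degenerate = TRUE))
    }
    return(list(t_statistic = sign(md) * Inf,
                p_two_tailed = .Machine$double.xmin, mean_diff = md,
                sem_diff = 0, df = n - 1L, n = n, degenerate = TRUE))
  }
  tval <- md / sem
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  list(t_statistic = tval, p_two_tailed = p, mean_diff = md,
       sem_diff = sem, df = n - 1L, n = n, degenerate = FALSE)
}

#' Percent change of a quantity
#'
#' `100 * (after - before) / before`; e.g. a delta-`<P2>` of 0.082 falling
#' to 0.069 is a change of -15.9%, i.e. about 16% smaller.
#'
#' @param before Baseline value, non-zero.
#' @param after Value after the intervention.
#' @return Signed percent change.
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) stop("percent change undefined for zero baseline",
                             call. = FALSE)
  100 * (after - before) / before
}

#' Standard error of the mean
#'
#' @param x Numeric vector, `n >= 2`.
#' @return `sd(x) / sqrt(n)`; 0 for identical values.
#' @export
sem <- function(x) {
  stopifnot(length(x) >= 2L)
  stats::sd(x) / sqrt(length(x))
}

#' Assemble a paper-style summary table with significance flags
#'
#' Aggregates a per-preparation fit report (as produced by [fit_records()])
#' into a mean +/- SEM grid with paired-t significance flags, in two
#' layouts:
#'
#' * `layout = "table1"` — sarcomere-length comparison: for each probe and
#'   quantity, control cells at SL 1.9 and 2.3 um; `star` marks p < 0.05 for
#'   the paired 1.9-vs-2.3 comparison.
#' * `layout = "table2"` — force-inhibitor comparison: cells for control at
#'   SL 1.9, inhibitor at 1.9 and inhibitor at 2.3; `star` marks the paired
#'   control-vs-inhibitor contrast at 1.9 um and `hash` the paired
#'   1.9-vs-2.3 contrast under the inhibitor.
#'
#' Quantities summarized per response kind: `pca50`, `n_h`, and for `<P2>`
#' additionally the responses at pCa 6 and 4.5 and the activation change
#' `delta` (the paper-style delta column averages per-preparation deltas);
#' for force additionally the fitted maximum `fmax`.  Missing or unmatched
#' pairs make that flag `NA` (reported, not fatal).  No multiple-testing
#' correction is applied: each flag is a single two-tailed test at `alpha`.
#'
#' @param fits Data frame fit report; required columns `trabecula_id`,
#'   `probe`, `sl_um`, `treatment`, `response_kind`, plus the quantity
#'   columns above.
#' @param layout `"table1"` or `"table2"`.
#' @param alpha Flag significance level (default 0.05).
#' @return Data frame of class `fp_summary_table`: one row per
#'   (probe, response_kind, quantity, condition) with `mean`, `sem`, `n`,
#'   `star`, `hash`, `p_star`, `p_hash`.
#' @export
build_summary_table <- function(fits, layout = c("table1", "table2"),
                                alpha = 0.05) {
  layout <- match.arg(layout)
  req <- c("trabecula_id", "probe", "sl_um", "treatment", "response_kind")
  miss <- setdiff(req, names(fits))
  if (length(miss)) {
    stop("fit report is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  conditions <- if (layout == "table1") {
    data.frame(sl_um = c(1.9, 2.3), treatment = "control",
               label = c("SL 1.9", "SL 2.3"), stringsAsFactors = FALSE)
  } else {
    data.frame(sl_um = c(1.9, 1.9, 2.3),
               treatment = c("control", "blebbistatin", "blebbistatin"),
               label = c("SL 1.9 control", "SL 1.9 blebbistatin",
                         "SL 2.3 blebbistatin"), stringsAsFactors = FALSE)
  }
  quantities <- list(
    p2 = intersect(c("pca50", "n_h", "resp_pca6", "resp_pca45", "delta"),
                   names(fits)),
    force = intersect(c("fmax", "pca50", "n_h"), names(fits))
  )

  rows <- list()
  for (probe in unique(fits$probe)) {
    for (kind in intersect(c("force", "p2"), unique(fits$response_kind))) {
      sub <- fits[fits$probe == probe & fits$response_kind == kind, ,
                  drop = FALSE]
      if (nrow(sub) == 0) next
      for (q in quantities[[kind]]) {
        cells <- lapply(seq_len(nrow(conditions)), function(i) {
          ci <- sub[sub$sl_um == conditions$sl_um[i] &
                      sub$treatment == conditions$treatment[i], ,
                    drop = FALSE]
          ci <- ci[!is.na(ci[[q]]), , drop = FALSE]
          ci
        })
        # paired contrasts: table1 star = cond1 vs cond2;
        # table2 star = cond1 vs cond2, hash = cond2 vs cond3
        p_star <- pair_p(cells[[1]], cells[[2]], q)
        p_hash <- if (layout == "table2") pair_p(cells[[2]], cells[[3]], q)
                  else NA_real_
        for (i in seq_len(nrow(conditions))) {
          ci <- cells[[i]]
          nn <- nrow(ci)
          star <- if (layout == "table1") {
            i == 2 && !is.na(p_star) && p_star < alpha
          } else {
            i == 2 && !is.na(p_star) && p_star < alpha
          }
          hash <- layout == "table2" && i == 3 && !is.na(p_hash) &&
            p_hash < alpha
          rows[[length(rows) + 1L]] <- data.frame(
            probe = probe, response_kind = kind, quantity = q,
            condition = conditions$label[i],
            mean = if (nn) mean(ci[[q]]) else NA_real_,
            sem = if (nn >= 2) sem(ci[[q]]) else NA_real_,
            n = nn,
            star = star, hash = hash,
            p_star = if (i == 2) p_star else NA_real_,
            p_hash = if (i == 3) p_hash else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "layout") <- layout
  attr(out, "footer") <-
    "flags are single two-tailed paired t-tests; no multiple-testing correction"
  class(out) <- c("fp_summary_table", class(out))
  out
}

# paired p-value for quantity q between two condition cells, matching on id
pair_p <- function(ca, cb, q) {
  ids <- intersect(ca$trabecula_id, cb$trabecula_id)
  if (length(ids) < 2L) return(NA_real_)
  a <- ca[[q]][match(ids, ca$trabecula_id)]
  b <- cb[[q]][match(ids, cb$trabecula_id)]
  res <- paired_t(paired_sample(ids, a, b))
  if (res$degenerate && res$sem_diff == 0 && res$mean_diff == 0) {
    return(NA_real_)  # identical pairs: no evidence either way, no star
  }
  res$p_two_tailed
}

#' Render a summary table as aligned text
#'
#' @param tbl An `fp_summary_table` from [build_summary_table()].
#' @param digits Significant digits for mean and SEM.
#' @return Character vector of lines (invisibly printed).
#' @export
format_summary_table <- function(tbl, digits = 3) {
  fmt_cell <- function(m, s, n, star, hash) {
    if (is.na(m)) return("--")
    sprintf("%.*g +/- %.*g (n=%d)%s%s", digits, m, digits,
            ifelse(is.na(s), 0, s), n,
            ifelse(star, " *", ""), ifelse(hash, " #", ""))
  }
  lines <- character(0)
  for (probe in unique(tbl$probe)) {
    lines <- c(lines, sprintf("== %s ==", probe))
    sub <- tbl[tbl$probe == probe, , drop = FALSE]
    for (kind in unique(sub$response_kind)) {
      sk <- sub[sub$response_kind == kind, , drop = FALSE]
      for (q in unique(sk$quantity)) {
        sq <- sk[sk$quantity == q, , drop = FALSE]
        cells <- vapply(seq_len(nrow(sq)), function(i) {
          fmt_cell(sq$mean[i], sq$sem[i], sq$n[i], sq$star[i], sq$hash[i])
        }, character(1))
        lines <- c(lines, sprintf("  %-6s %-10s %s", kind, q,
                                  paste(sprintf("[%s] %s", sq$condition,
                                                cells), collapse = "  ")))
      }
    }
  }
  lines <- c(lines, attr(tbl, "footer"))
  lines
}
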