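#' Screening record table
#'
#' Normalises a virtual-screening result table: one row per compound with
#' `compound_id`, `label` (`"active"`/`"inactive"`), `score` (kcal/mol,
#' lower is better, `NA` when the compound could not be docked) and
#' `docked`.  Compounds a model fails to dock are legitimate data — they
#' count as not retrieved in every metric downstream.
#'
#' @param compound_id character vector.
#' @param label `"active"` or `"inactive"` per compound.
#' @param score numeric scores, `NA` for undocked compounds.
#' @param docked logical; defaults to `!is.na(score)`.
#' @return data frame of class `screen_records`.
#' @export
screen_records <- function(compound_id, label, score,
                           docked = !is.na(score)) {
  label <- match.arg(as.character(label), c("active", "inactive"),
                     several.ok = TRUE)
  stopifnot(length(compound_id) == length(label),
            length(score) == length(label))
  if (anyDuplicated(compound_id)) stop("duplicate compound ids")
  if (any(!docked & !is.na(score)))
    stop("undocked compounds must not carry a score")
  if (any(docked & !is.finite(score)))
    stop("docked compounds must carry a finite score")
  structure(data.frame(compound_id = as.character(compound_id),
                       label = label, score = score, docked = docked,
                       stringsAsFactors = FALSE),
            class = c("screen_records", "data.frame"))
}

#' Read a screening table from CSV
#'
#' Expects columns `compound_id`, `label`, `score` and optionally
#' `docked` (inferred from missing scores when absent).
#'
#' @param path CSV path.
#' @return a [screen_records()] table.
#' @export
read_screen_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "label", "score")
  if (!all(need %in% names(tab)))
    stop("screen CSV must have columns: ", paste(need, collapse = ", "))
  docked <- if ("docked" %in% names(tab)) as.logical(tab$docked) else !is.na(tab$score)
  screen_records(tab$compound_id, tab$label, tab$score, docked)
}

#' Rank a screening table best-first
#'
#' Scored compounds are sorted by score ascending (lower = better);
#' undocked compounds are appended after all scored ones, in their input
#' order, so a model that cannot dock a compound never gets credit for
#' it.  Score ties are resolved by policy: `"average_rank"` keeps input
#' order and gives fractional credit in the AUC (tie-corrected rank-sum
#' semantics), `"worst_case"` orders inactives before actives within the
#' tie (pessimistic).
#'
#' @param records a [screen_records()] table (needs at least one active
#'   and one inactive).
#' @param tie_policy `"average_rank"` (default) or `"worst_case"`.
#' @return the reordered table, class `ranking`, with the tie policy
#'   attached as attribute `tie_policy`.
#' @export
build_ranking <- function(records, tie_policy = c("average_rank", "worst_case")) {
  tie_policy <- match.arg(tie_policy)
  if (!any(records$label == "active")) stop("no active compounds")
  if (!any(records$label == "inactive")) stop("no inactive compounds")
  scored <- records[records$docked, , drop = FALSE]
  undocked <- records[!records$docked, , drop = FALSE]
  if (nrow(scored)) {
    if (tie_policy == "worst_case") {
      o <- order(scored$score, scored$label != "inactive", method = "radix")
    } else {
      o <- order(scored$score, method = "radix")
    }
    scored <- scored[o, , drop = FALSE]
  }
  out <- rbind(scored, undocked)
  rownames(out) <- NULL
  structure(out, class = c("ranking", "screen_records", "data.frame"),
            tie_policy = tie_policy)
}

# tie groups in rank order: average_rank collapses equal scores (and the
# undocked block) into one group each, producing chord segments in the
# ROC curve; worst_case keeps per-record steps of the pessimistic order.
rank_groups <- function(ranking) {
  policy <- attr(ranking, "tie_policy") %||% "average_rank"
  n <- nrow(ranking)
  if (policy == "worst_case") return(seq_len(n))
  key <- ifelse(ranking$docked, as.character(ranking$score), "undocked")
  match(key, unique(key))
}

#' ROC curve of a ranking
#'
#' Cumulative true/false positive rates of the active-vs-inactive
#' ranking, with one point per distinct score threshold (tied scores and
#' the undocked block advance in one step, i.e. a chord) plus the fixed
#' endpoints (0,0) and (1,1).
#'
#' @param ranking a [build_ranking()] result.
#' @return data frame (`fpr`, `tpr`), class `roc_curve`, both columns
#'   non-decreasing from 0 to 1.
#' @export
roc_curve <- function(ranking) {
  if (!inherits(ranking, "ranking")) ranking <- build_ranking(ranking)
  grp <- rank_groups(ranking)
  act <- ranking$label == "active"
  n_act <- sum(act); n_inact <- sum(!act)
  tp <- cumsum(tapply(act, grp, sum)[as.character(unique(grp))])
  fp <- cumsum(tapply(!act, grp, sum)[as.character(unique(grp))])
  out <- data.frame(fpr = c(0, unname(fp) / n_inact),
                    tpr = c(0, unname(tp) / n_act))
  structure(out, class = c("roc_curve", "data.frame"))
}

#' Area under the ROC curve
#'
#' Trapezoidal integral of the ROC curve over the false-positive rate.
#' Under the `"average_rank"` tie policy this equals the tie-corrected
#' Mann-Whitney statistic `U / (n_act * n_inact)`.
#'
#' @param x a `roc_curve`, a `ranking`, or a [screen_records()] table
#'   (ranked with the default policy).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(x) {
  if (inherits(x, "roc_curve")) {
    n <- nrow(x)
    return(sum(diff(x$fpr) * (x$tpr[-1] + x$tpr[-n]) / 2))
  }
  auc(roc_curve(x))
}

#' Top-fraction enrichment factor (actives-to-inactives variant)
#'
#' Early-recognition metric over the best `fraction` of the ranking:
#' with `n_sel = floor(fraction * N)` compounds selected,
#' `EF = N_actives(sel) / N_inactives(sel)`.  This is a ratio of actives
#' to inactives *within* the selection, not the classical hit-rate
#' enrichment; its ideal-ranking maximum is given by
#' [max_enrichment_factor()].  Undocked compounds sit at the bottom of
#' the ranking and are never selected before scored ones.
#'
#' @param ranking a [build_ranking()] result (or raw records).
#' @param fraction selected fraction, strictly between 0 and 1 (default
#'   0.15).
#' @return the EF value; `Inf` when the selection contains no inactive.
#'   Display values are conventionally rounded half-up to 2 decimals
#'   ([round_half_up()]).
#' @export
enrichment_factor <- function(ranking, fraction = 0.15) {
  if (!inherits(ranking, "ranking")) ranking <- build_ranking(ranking)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_sel <- floor(fraction * nrow(ranking))
  if (n_sel == 0) stop("selection is empty at this fraction")
  top <- ranking$label[seq_len(n_sel)]
  n_act <- sum(top == "active")
  n_inact <- n_sel - n_act
  if (n_inact == 0) return(Inf)
  n_act / n_inact
}

#' Maximum attainable enrichment factor
#'
#' EF of the ideal ranking (all actives first): with
#' `n_sel = floor(fraction * (n_actives + n_inactives))` and
#' `m = min(n_actives, n_sel)`, the maximum is `m / (n_sel - m)`
#' (`Inf` when the selection can be filled with actives alone).
#'
#' @param n_actives,n_inactives library composition.
#' @param fraction selected fraction (default 0.15).
#' @return the maximal EF value (possibly `Inf`).
#' @export
max_enrichment_factor <- function(n_actives, n_inactives, fraction = 0.15) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_sel <- floor(fraction * (n_actives + n_inactives))
  if (n_sel == 0) stop("selection is empty at this fraction")
  m <- min(n_actives, n_sel)
  if (n_sel - m == 0) return(Inf)
  m / (n_sel - m)
}

#' Evaluate a ranking with all screening metrics
#'
#' @param ranking a [build_ranking()] result.
#' @param fraction EF fraction (default 0.15).
#' @return list with `auc`, `ef`, `ef_max`, `n_actives`, `n_inactives`,
#'   `n_docked`.
#' @export
screen_metrics <- function(ranking, fraction = 0.15) {
  if (!inherits(ranking, "ranking")) ranking <- build_ranking(ranking)
  n_act <- sum(ranking$label == "active")
  n_inact <- sum(ranking$label == "inactive")
  # a library too small for the fraction has no defined EF
  ef_defined <- floor(fraction * nrow(ranking)) >= 1
  list(auc = auc(ranking),
       ef = if (ef_defined) enrichment_factor(ranking, fraction) else NA_real_,
       ef_max = if (ef_defined)
         max_enrichment_factor(n_act, n_inact, fraction) else NA_real_,
       n_actives = n_act, n_inactives = n_inact,
       n_docked = sum(ranking$docked))
}
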