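#' Simulate the AI-assisted accept-or-adjust workflow
#'
#' Each observer reviews the AI-proposed CTR for every case.  The decision
#' is modelled as a tolerance comparison against the observer's own
#' (simulated) manual reading: if the AI value is within `accept_tol`
#' (relative, against the pair mean) of the observer's own value, the AI
#' value is accepted unchanged; otherwise the observer adjusts, and the
#' assisted value is the observer's own manual draw.  If the AI failed on a
#' case, the default-line fallback applies: the assisted value is the
#' observer's manual value and the decision is recorded as `"fallback"`.
#'
#' The default tolerance of +/- 1.8 percent is the empirical band within
#' which AI and manual readings were observed to be accepted without further
#' interaction; here it is the explicit parameter of the decision rule.
#'
#' @param pop a `phantom_population`.
#' @param ai_records AI-only measurement data.frame (one record per case).
#' @param observers list of [observer_model()]s.
#' @param accept_tol relative acceptance tolerance (default 0.018).
#' @param replicates integer vector, number of assisted replicates per
#'   observer (default `c(2, 1)`: observer 1 twice, observer 2 once).
#' @param session_offset seed displacement so assisted manual draws are
#'   independent of the pure-manual session's draws.
#' @return List with `records` (method `"ai_assisted"`) and `decisions`
#'   (case_id, observer_id, replicate, decision in
#'   accept/adjust/fallback).
#' @export
run_assisted <- function(pop, ai_records, observers, accept_tol = 0.018,
                         replicates = c(2L, 1L), session_offset = 1000003L) {
  stopifnot(inherits(pop, "phantom_population"), accept_tol >= 0,
            length(replicates) == length(observers))
  ai <- ai_records[match(pop$cases$case_id, ai_records$case_id), ,
                   drop = FALSE]
  if (anyNA(ai$case_id))
    stop("pairing error: missing AI record for some case(s)")
  rec_list <- list(); dec_list <- list()
  for (k in seq_along(observers)) {
    obs <- observers[[k]]
    for (r in seq_len(replicates[k])) {
      own <- simulate_manual(pop, obs, replicate = r, method = "ai_assisted",
                             seed_offset = session_offset)
      rel_diff <- abs(ai$ctr - own$ctr) / ((ai$ctr + own$ctr) / 2)
      accept <- !ai$failed & rel_diff <= accept_tol
      decision <- ifelse(ai$failed, "fallback",
                         ifelse(accept, "accept", "adjust"))
      value <- ifelse(accept, ai$ctr, own$ctr)
      rec_list[[length(rec_list) + 1L]] <-
        data.frame(case_id = pop$cases$case_id, method = "ai_assisted",
                   observer_id = obs$observer_id, replicate = r,
                   ctr = value, failed = FALSE, stringsAsFactors = FALSE)
      dec_list[[length(dec_list) + 1L]] <-
        data.frame(case_id = pop$cases$case_id,
                   observer_id = obs$observer_id, replicate = r,
                   decision = decision, stringsAsFactors = FALSE)
    }
  }
  list(records = do.call(rbind, rec_list),
       decisions = do.call(rbind, dec_list))
}

#' Grade AI outcomes from the assisted workflow
#'
#' Grading rule: an AI calculation failure is `poor`; an outcome accepted by
#' both observers independently (their first replicates) is `excellent`; any
#' outcome that required adjustment by either observer is `good`.  The three
#' grades partition the cases.
#'
#' @param decisions decision data.frame from [run_assisted()].
#' @param ai_records AI-only measurement data.frame (for failure flags).
#' @param cases optional case table with `group` for a per-group breakdown.
#' @return An object of class `grading_summary`: counts, proportions and
#'   (if `cases` given) a group-by-grade table.
#' @export
grade_outcomes <- function(decisions, ai_records, cases = NULL) {
  ids <- unique(ai_records$case_id)
  first <- decisions[decisions$replicate == 1L, , drop = FALSE]
  obs_ids <- unique(first$observer_id)
  if (length(obs_ids) < 2L)
    stop("incomplete study: grading needs first-replicate decisions from ",
         "two observers")
  d1 <- first[first$observer_id == obs_ids[1L], ]
  d2 <- first[first$observer_id == obs_ids[2L], ]
  dec1 <- d1$decision[match(ids, d1$case_id)]
  dec2 <- d2$decision[match(ids, d2$case_id)]
  if (anyNA(dec1) || anyNA(dec2))
    stop("incomplete study: missing decision for some case(s)")
  failed <- ai_records$failed[match(ids, ai_records$case_id)]
  grade <- ifelse(failed, "poor",
                  ifelse(dec1 == "accept" & dec2 == "accept",
                         "excellent", "good"))
  counts <- c(excellent = sum(grade == "excellent"),
              good = sum(grade == "good"),
              poor = sum(grade == "poor"))
  by_group <- NULL
  if (!is.null(cases)) {
    grp <- cases$group[match(ids, cases$case_id)]
    by_group <- table(group = grp,
                      grade = factor(grade,
                                     c("excellent", "good", "poor")))
  }
  structure(list(n_excellent = counts[["excellent"]],
                 n_good = counts[["good"]], n_poor = counts[["poor"]],
                 proportions = counts / length(ids),
                 n_cases = length(ids), by_group = by_group,
                 grades = data.frame(case_id = ids, grade = grade,
                                     stringsAsFactors = FALSE)),
            class = "grading_summary")
}

#' @export
print.grading_summary <- function(x, ...) {
  cat(sprintf(
    "AI outcome grading (n=%d): excellent %d (%.1f%%), good %d (%.1f%%), poor %d (%.1f%%)\n",
    x$n_cases, x$n_excellent, 100 * x$proportions[["excellent"]],
    x$n_good, 100 * x$proportions[["good"]],
    x$n_poor, 100 * x$proportions[["poor"]]))
  if (!is.null(x$by_group)) print(x$by_group)
  invisible(x)
}

#' Per-case consensus values for a measurement method
#'
#' For replicated methods, the per-case consensus is the arithmetic mean of
#' all constituent readings of the design (e.g. observer 1's two replicates
#' and observer 2's one).  Cases missing any constituent, or with a failed
#' constituent, are excluded from the consensus and counted.
#' Single-record methods (`ai_only`, `reference`) pass through, with failed
#' records excluded and counted.
#'
#' @param records measurement data.frame (may contain several methods).
#' @param method method to aggregate.
#' @return List with `values` (data.frame case_id, ctr) and `n_excluded`.
#' @export
consensus_values <- function(records, method) {
  sub <- records[records$method == method, , drop = FALSE]
  if (nrow(sub) == 0L) stop("input error: no records for method ", method)
  series <- unique(sub[, c("observer_id", "replicate")])
  n_series <- nrow(series)
  ids <- unique(sub$case_id)
  ok <- sub[!sub$failed, , drop = FALSE]
  agg <- tapply(ok$ctr, ok$case_id, mean)
  cnt <- tapply(ok$ctr, ok$case_id, length)
  complete <- names(cnt)[cnt == n_series]
  keep <- ids[ids %in% complete]
  list(values = data.frame(case_id = keep,
                           ctr = as.numeric(agg[keep]),
                           stringsAsFactors = FALSE),
       n_excluded = length(ids) - length(keep))
}

#' Run the full observer/method validation study on a phantom population
#'
#' Emits, for every case: a reference record (designed true CTR, or CTR
#' measured from ground-truth masks), three manual records (observer 1
#' replicates 1-2, observer 2 replicate 1), one AI-only record, and the
#' assisted records of the accept-or-adjust workflow, plus the
#' excellent/good/poor grading.  Fully reproducible from the seeds carried
#' by the population and the models.
#'
#' @param pop a `phantom_population`.
#' @param observers list of two [observer_model()]s.
#' @param ai_model an [ai_error_model()].
#' @param accept_tol assisted-workflow acceptance tolerance.
#' @param reference `"truth"` (designed CTR) or `"truth_mask"` (CTR measured
#'   from the rendered ground-truth masks).
#' @param replicates assisted/manual replication design (default 2+1).
#' @return An object of class `ctr_study`: list with `measurements` (all
#'   methods stacked), `decisions`, `grading`, `cases`.
#' @export
run_study <- function(pop, observers = default_observers(),
                      ai_model = ai_error_model(), accept_tol = 0.018,
                      reference = c("truth", "truth_mask"),
                      replicates = c(2L, 1L)) {
  stopifnot(inherits(pop, "phantom_population"), length(observers) == 2L)
  reference <- match.arg(reference)
  ref <- if (reference == "truth") {
    data.frame(case_id = pop$cases$case_id, method = "reference",
               observer_id = "truth", replicate = 1L,
               ctr = pop$cases$true_ctr, failed = FALSE,
               stringsAsFactors = FALSE)
  } else measure_population(pop, source = "truth")$records
  manual <- do.call(rbind, unlist(lapply(seq_along(observers), function(k)
    lapply(seq_len(replicates[k]), function(r)
      simulate_manual(pop, observers[[k]], r))), recursive = FALSE))
  ai <- simulate_ai_only(pop, ai_model)
  assisted <- run_assisted(pop, ai, observers, accept_tol = accept_tol,
                           replicates = replicates)
  grading <- grade_outcomes(assisted$decisions, ai, pop$cases)
  structure(list(measurements = rbind(ref, manual, ai, assisted$records),
                 decisions = assisted$decisions, grading = grading,
                 cases = pop$cases),
            class = "ctr_study")
}

#' @export
print.ctr_study <- function(x, ...) {
  cat("ctr_study:", nrow(x$cases), "cases,",
      nrow(x$measurements), "measurement records\n")
  print(x$grading)
  invisible(x)
}
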