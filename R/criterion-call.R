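# CriterionCall: one evaluated criterion with direction, strength and an
# audit rationale.  Calls are plain S3 lists so that reports serialise
# naturally to JSON.

#' Construct a criterion call
#'
#' A criterion call records the outcome of evaluating one ACMG/AMP
#' criterion: whether it applies, at which modulated strength, and why.
#' Unapplied calls (`applied = FALSE`) are kept in the audit trail so the
#' report always enumerates all 28 criteria.
#'
#' @param criterion One of the 28 criterion codes (see [acmg_criteria()]).
#' @param strength Strength code (`"A"`, `"VS"`, `"S"`, `"M"`, `"P"`) or
#'   `NA` for unapplied calls.  Must be one of the modulations allowed for
#'   the criterion.
#' @param applied Logical; whether the criterion counts as evidence.
#' @param rationale Free-text rationale, opening with a clause tag.
#' @param score Optional numeric scoring-system (SS) total for the scored
#'   criteria (PM3, PM6, PS2).
#' @return An object of class `criterion_call`.
#' @export
criterion_call <- function(criterion, strength = NA_character_,
                           applied = TRUE, rationale = "", score = NULL) {
  if (!is.character(criterion) || length(criterion) != 1 ||
      !(criterion %in% acmg_criteria())) {
    stop("unknown criterion code: ", paste(criterion, collapse = ", "))
  }
  if (applied) {
    ok <- allowed_strengths(criterion)
    if (is.null(ok)) {
      stop(criterion, " is never applied and cannot carry an applied call")
    }
    if (!is.character(strength) || length(strength) != 1 || !(strength %in% ok)) {
      stop("strength ", strength, " is not an allowed modulation of ",
           criterion, " (allowed: ", paste(ok, collapse = ", "), ")")
    }
  }
  structure(
    list(criterion = criterion,
         direction = criterion_direction(criterion),
         strength = if (applied) strength else NA_character_,
         applied = isTRUE(applied),
         rationale = rationale,
         score = score),
    class = "criterion_call"
  )
}

#' @export
print.criterion_call <- function(x, ...) {
  lab <- if (x$applied) paste0(x$criterion, "_", x$strength) else
    paste0(x$criterion, " (not applied)")
  cat(lab, if (nzchar(x$rationale)) paste0("- ", x$rationale) else "", "\n")
  invisible(x)
}

#' @export
format.criterion_call <- function(x, ...) {
  if (x$applied) paste0(x$criterion, "_", x$strength) else x$criterion
}

# Compact "PM2_M"-style labels for a list of calls (applied only).
call_labels <- function(calls) {
  calls <- applied_calls(calls)
  unname(vapply(calls, format, character(1)))
}

#' Keep only applied calls
#'
#' @param calls List of [criterion_call()] objects (possibly `NULL` entries).
#' @return List of the applied calls.
#' @export
applied_calls <- function(calls) {
  calls <- Filter(Negate(is.null), calls)
  Filter(function(x) isTRUE(x$applied), calls)
}

# Internal shorthand: an unapplied audit placeholder.
unapplied_call <- function(criterion, rationale) {
  structure(
    list(criterion = criterion,
         direction = criterion_direction(criterion),
         strength = NA_character_,
         applied = FALSE,
         rationale = rationale,
         score = NULL),
    class = "criterion_call"
  )
}
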