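# JSON export/import of piecewise fit reports.

#' Write / read a piecewise fit report as JSON
#'
#' The report carries the parameter names `a11, a10, ts, a22, a21, a20`
#' with `ci_lo`/`ci_hi` companions and the `r2` summaries, so fits can move
#' between pipeline stages as plain text.
#'
#' @param fit a `piecewise_fit`.
#' @param path JSON path.
#' @return `path` invisibly (write) or a `piecewise_fit` (read; the
#'   original curve is not stored in the report).
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "piecewise_fit"))
  rep <- list(
    parameters = as.list(fit$coef),
    ci_lo = as.list(setNames(fit$ci[, "lo"], rownames(fit$ci))),
    ci_hi = as.list(setNames(fit$ci[, "hi"], rownames(fit$ci))),
    r2 = fit$r2,
    ts_fixed = fit$ts_fixed,
    level = fit$level,
    jump = fit$jump,
    physical = fit$physical
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("a11", "a10", "ts", "a22", "a21", "a20")
  if (!all(need %in% names(rep$parameters)))
    stop("fit report lacks parameters: ",
         paste(setdiff(need, names(rep$parameters)), collapse = ", "))
  est <- unlist(rep$parameters)[need]
  ci <- cbind(lo = unlist(rep$ci_lo)[need], hi = unlist(rep$ci_hi)[need])
  structure(list(coef = est, ci = ci, ts_fixed = isTRUE(rep$ts_fixed),
                 level = rep$level, r2 = rep$r2, jump = rep$jump,
                 physical = isTRUE(rep$physical), curve = NULL),
            class = "piecewise_fit")
}
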