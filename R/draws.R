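#' @keywords internal
#' Extract the iterations x chains x parameters draw array from a fit
draws_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.list(x) && !is.null(x$draws)) return(x$draws)
  stop("cannot extract a draws array from object of class ",
       paste(class(x), collapse = "/"))
}

#' Flatten a draws array to a (chains*iterations) x parameters matrix
#' @keywords internal
draws_matrix <- function(x) {
  a <- draws_array(x)
  d <- dim(a)
  m <- matrix(a, nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- dimnames(a)[[3]]
  m
}

#' Write posterior draws to a long CSV
#'
#' Serializes the draws of a spline or mixed-model fit (or a bare
#' iterations x chains x parameters array) as long tabular text with columns
#' `chain`, `iteration`, `parameter`, `value` at full double precision, so a
#' read-back reproduces the draw array exactly.
#'
#' @param draws A fit object with a `$draws` array or a 3-d draws array.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  a <- draws_array(draws)
  d <- dim(a)
  if (any(d == 0)) stop("cannot write empty draws")
  pars <- dimnames(a)[[3]]
  if (is.null(pars)) pars <- paste0("par", seq_len(d[3]))
  long <- data.frame(
    chain = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    iteration = rep(seq_len(d[1]), times = d[2] * d[3]),
    parameter = rep(pars, each = d[1] * d[2]),
    value = sprintf("%.17g", as.vector(a)),
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("could not write draws to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read posterior draws written by [write_draws()]
#'
#' @param path CSV produced by [write_draws()].
#' @return An iterations x chains x parameters array with parameter
#'   dimnames, identical to the serialized array.
#' @export
read_draws <- function(path) {
  if (!file.exists(path)) stop("draw file not found: ", path)
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c("integer", "integer",
                                         "character", "numeric"))
  stopifnot(all(c("chain", "iteration", "parameter", "value") %in% names(long)))
  pars <- unique(long$parameter)
  n_ch <- max(long$chain)
  n_it <- max(long$iteration)
  a <- array(NA_real_, dim = c(n_it, n_ch, length(pars)),
             dimnames = list(NULL, NULL, pars))
  idx <- cbind(long$iteration, long$chain, match(long$parameter, pars))
  a[idx] <- long$value
  if (anyNA(a)) stop("draw file is not a complete chain x iteration grid")
  a
}
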