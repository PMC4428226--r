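#' Read a pattern count table
#'
#' Reads a tab-separated count table: a header line `pattern<TAB>count`
#' followed by one row per observed methylation pattern (binary string) and
#' its non-negative integer read count.  Lines starting with `#` and blank
#' lines are ignored.  Ragged pattern lengths, non-binary characters,
#' negative or non-integer counts and duplicated patterns are format errors
#' reported with their line number.
#'
#' @param path Path to the file.
#' @return A [pattern_counts()] object; `n` is inferred from the pattern
#'   length.
#' @seealso [write_counts()], [run_estimate()]
#' @export
read_counts <- function(path) {
  tab <- read_two_columns(path, c("pattern", "count"))
  counts <- suppressWarnings(as.numeric(tab$value))
  bad <- is.na(counts) | counts < 0 | counts != trunc(counts)
  if (any(bad))
    stop(format_error(path, tab$line[bad][1L],
                      "count is not a non-negative integer: ",
                      tab$value[bad][1L]))
  check_pattern_column(path, tab)
  pattern_counts(tab$pattern, counts)
}

#' Read a pattern distribution table
#'
#' Same layout as [read_counts()] but the second column holds
#' probabilities, which must be non-negative and sum to 1 within `tol`.
#' The header's second field may be any name (`count`, `prob`,
#' `theta`, ...).
#'
#' @param path Path to the file.
#' @param tol Tolerance on the probability sum (default 1e-6).
#' @return Named numeric distribution over patterns.
#' @export
read_theta <- function(path, tol = 1e-6) {
  tab <- read_two_columns(path, NULL)
  p <- suppressWarnings(as.numeric(tab$value))
  bad <- is.na(p) | p < 0
  if (any(bad))
    stop(format_error(path, tab$line[bad][1L],
                      "probability is negative or unreadable: ",
                      tab$value[bad][1L]))
  check_pattern_column(path, tab)
  theta <- stats::setNames(p, tab$pattern)
  validate_distribution(theta, tol)
  theta
}

# Shared two-column TSV reader; returns data.frame(pattern, value, line).
read_two_columns <- function(path, header) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("no data in ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L))
    stop(format_error(path, idx[nf != 2L][1L],
                      "expected two tab-separated fields"))
  head_fields <- fields[[1L]]
  if (!is.null(header) && !identical(tolower(head_fields), header))
    stop(format_error(path, idx[1L], "expected header '",
                      paste(header, collapse = "\t"), "'"))
  if (length(idx) < 2L) stop("no data rows in ", path)
  body <- fields[-1L]
  data.frame(pattern = trimws(vapply(body, `[`, "", 1L)),
             value = trimws(vapply(body, `[`, "", 2L)),
             line = idx[-1L], stringsAsFactors = FALSE)
}

check_pattern_column <- function(path, tab) {
  bad <- grepl("[^01]", tab$pattern) | nchar(tab$pattern) == 0L
  if (any(bad))
    stop(format_error(path, tab$line[bad][1L],
                      "pattern is not a binary string: ", tab$pattern[bad][1L]))
  lens <- nchar(tab$pattern)
  if (any(lens != lens[1L]))
    stop(format_error(path, tab$line[lens != lens[1L]][1L],
                      "pattern length differs from the first row"))
  dup <- duplicated(tab$pattern)
  if (any(dup))
    stop(format_error(path, tab$line[dup][1L],
                      "duplicated pattern: ", tab$pattern[dup][1L]))
  invisible(tab)
}

format_error <- function(path, line, ...) {
  paste0(path, ": line ", line, ": ", ...)
}

#' Write a pattern count table
#'
#' @param counts A [pattern_counts()] object.
#' @param path Output path.
#' @param metadata Optional character vector written as leading `#` comment
#'   lines.
#' @param keep_zero Also write rows with zero counts (default drops them).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, metadata = NULL, keep_zero = FALSE) {
  counts <- as_pattern_counts(counts)
  keep <- if (keep_zero) rep(TRUE, length(counts$patterns))
          else counts$counts > 0L
  lines <- c(if (length(metadata)) paste0("# ", metadata),
             "pattern\tcount",
             paste(counts$patterns[keep], counts$counts[keep], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write an estimate table
#'
#' Tab-separated table with columns `pattern`, `y`, `y_over_N`,
#' `theta_hat`, `spurious` (true/false), in lexicographic pattern order by
#' default.  Frequencies are written with 6 significant digits; spurious
#' patterns print `theta_hat` as exactly 0.
#'
#' @param fit A [estimate_patterns()] fit.
#' @param path Output path.
#' @param order `"pattern"` (lexicographic, default) or `"frequency"`
#'   (descending `theta_hat`).
#' @param all_patterns Include zero-read patterns searched by the fit.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(fit, path, order = c("pattern", "frequency"),
                            all_patterns = FALSE) {
  stopifnot(inherits(fit, "pattern_fit"))
  order <- match.arg(order)
  tab <- summary(fit, all_patterns = all_patterns)$table
  if (order == "frequency")
    tab <- tab[order(-tab$theta_hat, tab$pattern, method = "radix"), ]
  lines <- c("pattern\ty\ty_over_N\ttheta_hat\tspurious",
             sprintf("%s\t%d\t%s\t%s\t%s", tab$pattern, tab$y,
                     signif6(tab$y_over_N), signif6(tab$theta_hat),
                     ifelse(tab$spurious, "true", "false")))
  writeLines(lines, path)
  invisible(path)
}

signif6 <- function(x) {
  out <- vapply(signif(x, 6L), format, "", scientific = FALSE,
                trim = TRUE, digits = 15L)
  out[x == 0] <- "0"
  out
}

#' Estimate workflow: count file in, estimate table out
#'
#' Reads a count table, fits [estimate_patterns()] and writes the estimate
#' table with [write_estimates()], echoing all parameters of the run to the
#' log (via [message()]) so the run can be reproduced.
#'
#' @param counts_path Input count table (see [read_counts()]).
#' @param epsilon Non-conversion rate.
#' @param eta Sequencing error rate: scalar, numeric vector, or a
#'   comma-separated string such as `"0.008,0.006"`.
#' @param mode `"fast"` or `"slow"`.
#' @param out_path Output estimate table.
#' @inheritParams estimate_patterns
#' @inheritParams write_estimates
#' @return The `pattern_fit`, invisibly.
#' @export
run_estimate <- function(counts_path, epsilon, eta, mode = "fast", out_path,
                         zero_tol = 1e-5, max_iter = 1e5L, force = FALSE,
                         order = "pattern", all_patterns = FALSE) {
  eta <- parse_eta(eta)
  counts <- read_counts(counts_path)
  message("estimate: counts=", counts_path, " n=", counts$n,
          " N_read=", counts$N, " epsilon=", epsilon,
          " eta=", paste(eta, collapse = ","), " mode=", mode,
          " zero_tol=", zero_tol, " max_iter=", max_iter)
  fit <- estimate_patterns(counts, epsilon = epsilon, eta = eta, mode = mode,
                           zero_tol = zero_tol, max_iter = max_iter,
                           force = force)
  write_estimates(fit, out_path, order = order, all_patterns = all_patterns)
  message("estimate: logLik=", format(fit$logLik), " iterations=",
          fit$iterations, " converged=", fit$converged,
          " boundary_snaps=", length(fit$boundary_snaps),
          " spurious=", length(fit$spurious), " -> ", out_path)
  invisible(fit)
}

#' Simulate workflow: distribution file in, count file out
#'
#' @param theta_path True distribution table (see [read_theta()]).
#' @param n_reads Number of reads.
#' @param epsilon,eta Error rates (`eta` as in [run_estimate()]).
#' @param seed Integer seed; recorded in the output metadata.
#' @param out_path Output count table; simulation parameters are written as
#'   `#` metadata lines.  With `truth_path`, the latent true-pattern counts
#'   are written there as a companion table.
#' @param truth_path Optional path for the latent true-pattern counts.
#' @return The `pattern_sim`, invisibly.
#' @export
run_simulate <- function(theta_path, n_reads, epsilon, eta, seed, out_path,
                         truth_path = NULL) {
  eta <- parse_eta(eta)
  theta <- read_theta(theta_path)
  model <- error_model(epsilon, eta)
  message("simulate: theta=", theta_path, " n_reads=", n_reads,
          " epsilon=", epsilon, " eta=", paste(eta, collapse = ","),
          " seed=", seed)
  sim <- simulate_reads(theta, n_reads, model, seed = seed)
  meta <- c(paste0("simulated from ", theta_path),
            paste0("n_reads=", n_reads, " epsilon=", epsilon,
                   " eta=", paste(eta, collapse = ","), " seed=", seed))
  write_counts(sim$counts, out_path, metadata = meta)
  if (!is.null(truth_path))
    write_counts(sim$true_counts, truth_path,
                 metadata = c(meta, "latent true pattern counts"))
  message("simulate: ", length(sim$counts$patterns),
          " observed patterns -> ", out_path)
  invisible(sim)
}

#' Evaluate workflow: truth + estimate table in, TPR/FPR table out
#'
#' Reads a true distribution and an estimate table (as written by
#' [run_estimate()]), computes [tpr_fpr_curve()] for both test statistics —
#' the estimated frequency and the naive proportion `y/N` — and writes one
#' block per statistic, tagged in a `statistic` column.
#'
#' @param truth_path True distribution table.
#' @param estimate_path Estimate table.
#' @param out_path Output TSV.
#' @return The combined data frame, invisibly.
#' @export
run_evaluate <- function(truth_path, estimate_path, out_path) {
  truth <- read_theta(truth_path)
  est <- utils::read.delim(estimate_path, comment.char = "#",
                           colClasses = c(pattern = "character"))
  need <- c("pattern", "y", "y_over_N", "theta_hat")
  if (!all(need %in% names(est)))
    stop(estimate_path, ": expected columns ",
         paste(need, collapse = ", "))
  if (any(nchar(est$pattern) != nchar(names(truth)[1L])))
    stop("pattern universes differ: estimate table has patterns of ",
         "different length than ", truth_path, ": ",
         paste(est$pattern[nchar(est$pattern) != nchar(names(truth)[1L])],
               collapse = ", "))
  est <- est[est$y > 0, ]
  message("evaluate: truth=", truth_path, " estimate=", estimate_path,
          " patterns=", nrow(est))
  out <- rbind(
    cbind(statistic = "theta_hat",
          tpr_fpr_curve(stats::setNames(est$theta_hat, est$pattern), truth)),
    cbind(statistic = "y_over_N",
          tpr_fpr_curve(stats::setNames(est$y_over_N, est$pattern), truth)))
  utils::write.table(out, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("evaluate: -> ", out_path)
  invisible(out)
}

# "0.02" or "0.008,0.006,..." or numeric -> numeric vector
parse_eta <- function(eta) {
  if (is.character(eta))
    eta <- as.numeric(strsplit(paste(eta, collapse = ","), ",")[[1L]])
  if (anyNA(eta)) stop("could not parse 'eta'")
  eta
}
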