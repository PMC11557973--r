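#' Read a per-system binding free-energy table
#'
#' Expects tab-separated columns \code{peptide}, \code{guest},
#' \code{membrane}, \code{deltaG}. The package ships the published whole-
#' peptide free energies in this layout:
#' \code{system.file("extdata", "deltag_table.tsv", package = "membind")}.
#'
#' @param path TSV file.
#' @return Data frame with the four columns.
#' @export
read_deltag_table <- function(path) {
  if (!file.exists(path)) stop("no such deltaG table: ", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("peptide", "guest", "membrane", "deltaG")
  if (!all(need %in% names(df))) {
    stop("deltaG table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Pair native and labelled binding free energies
#'
#' For each (peptide, membrane) key present for both guest residues, emits
#' one pair with the native guest's free energy as x and the labelled
#' guest's as y. Keys present for only one guest are an error.
#'
#' @param table Data frame as from [read_deltag_table()].
#' @param native_guest Guest label of the native residue (default "W",
#'   tryptophan).
#' @param labelled_guest Guest label of the fluorophore-bearing residue
#'   (default "WB", BODIPY-tryptophan).
#' @return An object of class \code{DeltaGPairs}: data frame with columns
#'   peptide, membrane, native, labelled, x, y ordered by peptide then
#'   membrane.
#' @export
pair_deltag <- function(table, native_guest = "W", labelled_guest = "WB") {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop("empty deltaG table")
  }
  a <- table[table$guest == native_guest, ]
  b <- table[table$guest == labelled_guest, ]
  key <- function(d) paste(d$peptide, d$membrane, sep = "|")
  ka <- key(a); kb <- key(b)
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    stop("duplicate (peptide, membrane) keys in the deltaG table")
  }
  unmatched <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(unmatched)) {
    stop("keys present for only one guest: ",
         paste(sort(unmatched), collapse = ", "))
  }
  if (!nrow(a)) stop("no rows for guests ", native_guest, "/", labelled_guest)
  m <- match(ka, kb)
  out <- data.frame(peptide = a$peptide, membrane = a$membrane,
                    native = native_guest, labelled = labelled_guest,
                    x = a$deltaG, y = b$deltaG[m],
                    stringsAsFactors = FALSE)
  out <- out[order(out$peptide, out$membrane), ]
  rownames(out) <- NULL
  if (any(!is.finite(out$x)) || any(!is.finite(out$y))) {
    stop("non-finite deltaG values in the table")
  }
  class(out) <- c("DeltaGPairs", class(out))
  out
}

#' Ordinary least squares fit of labelled against native free energies
#'
#' Classical OLS of y on x with two-sided confidence intervals from the
#' t distribution on n - 2 degrees of freedom.
#'
#' @param pairs A [pair_deltag()] result (or any data frame with x and y).
#' @param confidence Confidence level for the interval half-widths.
#' @return An object of class \code{RegressionResult}: list with
#'   \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{slope_ci_halfwidth}, \code{intercept_ci_halfwidth},
#'   \code{confidence}, \code{n}, \code{residuals} and \code{degenerate}
#'   (TRUE for the exact two-point fit, whose intervals are undefined).
#' @export
ols_fit <- function(pairs, confidence = 0.95) {
  stopifnot(is.data.frame(pairs), all(c("x", "y") %in% names(pairs)),
            confidence > 0, confidence < 1)
  n <- nrow(pairs)
  if (n < 2) stop("need at least 2 pairs")
  if (length(unique(pairs$x)) < 2) {
    stop("degenerate fit: all x values identical")
  }
  fit <- lm(y ~ x, data = pairs)
  co <- coef(fit)
  res <- as.numeric(residuals(fit))
  sst <- sum((pairs$y - mean(pairs$y))^2)
  # constant y: zero explained and zero total variance, reported as 0
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 0
  if (n == 2) {
    return(structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                          r_squared = 1, slope_ci_halfwidth = NA_real_,
                          intercept_ci_halfwidth = NA_real_,
                          confidence = confidence, n = n, residuals = res,
                          degenerate = TRUE),
                     class = "RegressionResult"))
  }
  se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  tq <- qt(1 - (1 - confidence) / 2, df = n - 2)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2,
                 slope_ci_halfwidth = unname(tq * se[2]),
                 intercept_ci_halfwidth = unname(tq * se[1]),
                 confidence = confidence, n = n, residuals = res,
                 degenerate = FALSE),
            class = "RegressionResult")
}

#' Headline labelling shift
#'
#' The labelling shift is reported operationally as the intercept of the
#' labelled-vs-native regression with its confidence half-width (the
#' published convention, even though the fitted slope is below one). A
#' companion estimate, the mean paired difference \eqn{\bar{y - x}} with its
#' t-based half-width, is reported alongside for comparison.
#'
#' @param result A [ols_fit()] result.
#' @param pairs The pairs the fit was computed from; required for the
#'   paired-difference companion estimate.
#' @return List with \code{ddg}, \code{ci_halfwidth} (intercept convention),
#'   \code{method}, and \code{paired} (list with \code{ddg},
#'   \code{ci_halfwidth}, \code{method}) when pairs are supplied.
#' @export
ddg_headline <- function(result, pairs = NULL) {
  stopifnot(inherits(result, "RegressionResult"))
  out <- list(ddg = result$intercept,
              ci_halfwidth = result$intercept_ci_halfwidth,
              method = "regression_intercept")
  if (!is.null(pairs)) {
    d <- pairs$y - pairs$x
    n <- length(d)
    hw <- if (n >= 2 && sd(d) > 0) {
      qt(1 - (1 - result$confidence) / 2, df = n - 1) * sd(d) / sqrt(n)
    } else 0
    out$paired <- list(ddg = mean(d), ci_halfwidth = hw,
                       method = "mean_paired_difference")
  }
  out
}
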