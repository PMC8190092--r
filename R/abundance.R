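#' Condition order of the light regime
#'
#' Growth light, high light, then five days of low-light recovery. This
#' fixed order is the abscissa of the trajectory fits (integer coding
#' 0..6).
#' @export
condition_levels <- function() c("GL", "HL", paste0("LL", 1:5))

#' Long-format protein abundance table
#'
#' @param df data.frame with columns `protein`, `condition`, `replicate`,
#'   `abundance` (>= 0). `condition` must use the labels of
#'   [condition_levels()].
#' @return the validated data.frame of class `abundance_table`, with
#'   `condition` as an ordered factor.
#' @export
abundance_table <- function(df) {
  need <- c("protein", "condition", "replicate", "abundance")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (!all(df$condition %in% condition_levels()))
    stop("unknown condition labels; expected ",
         paste(condition_levels(), collapse = ", "))
  if (any(df$abundance < 0)) stop("abundances must be non-negative")
  df$condition <- factor(df$condition, levels = condition_levels())
  class(df) <- c("abundance_table", "data.frame")
  df
}

#' Normalise abundances to a reference condition
#'
#' Divides every value of a protein by that protein's replicate-mean
#' abundance in the reference condition, yielding relative units in which
#' the reference mean is exactly 1. Proteins whose reference mean is zero
#' cannot be normalised; they are dropped and listed in the `dropped`
#' attribute. Idempotent: normalising an already normalised table changes
#' nothing.
#'
#' @param table an [abundance_table()].
#' @param reference condition label, default `"GL"`.
#' @return normalised `abundance_table`; attribute `dropped` holds the
#'   protein identifiers removed for zero reference mean.
#' @export
normalize_to_reference <- function(table, reference = "GL") {
  stopifnot(inherits(table, "abundance_table"))
  if (!reference %in% levels(table$condition) ||
      !any(table$condition == reference))
    stop("reference condition absent from table: ", reference)
  ref_means <- tapply(table$abundance[table$condition == reference],
                      table$protein[table$condition == reference], mean)
  dropped <- names(ref_means)[ref_means == 0]
  missing_ref <- setdiff(unique(table$protein), names(ref_means))
  dropped <- c(dropped, missing_ref)
  out <- table[!(table$protein %in% dropped), , drop = FALSE]
  out$abundance <- out$abundance / as.numeric(ref_means[as.character(out$protein)])
  if (length(dropped) > 0)
    message(length(dropped), " protein(s) dropped (zero or missing reference): ",
            paste(dropped, collapse = ", "))
  attr(out, "dropped") <- dropped
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Polynomial trajectory fit with adjusted R-squared
#'
#' Ordinary least-squares polynomial of the given degree (default 4, the
#' degree used for abundance time courses across a seven-condition light
#' regime), with `R^2 = 1 - SS_res / SS_tot` and
#' `adjusted R^2 = 1 - (1 - R^2) (n - 1) / (n - degree - 1)` (the degree
#' counts the parameters, the intercept is excluded).
#'
#' @param x numeric predictor (e.g. condition indices 0..6).
#' @param y numeric response (e.g. relative abundances).
#' @param degree polynomial degree; requires at least `degree + 2` distinct
#'   `x` values so the adjusted R-squared is defined.
#' @return list of class `trajectory_fit`: `coefficients` (lowest order
#'   first, length `degree + 1`), `r2`, `adj_r2`, `degree`, `n`,
#'   `fitted`, `residuals`.
#' @export
fit_trajectory <- function(x, y, degree = 4) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (length(unique(x)) < degree + 2)
    stop("need at least degree + 2 distinct x values (adjusted R^2 undefined at exact interpolation)")
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  co <- unname(stats::coef(fit))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - degree - 1)
  structure(list(coefficients = co, r2 = r2, adj_r2 = adj,
                 degree = degree, n = n,
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::residuals(fit))),
            class = "trajectory_fit")
}

#' Evaluate a fitted trajectory
#' @param fit a `trajectory_fit`.
#' @param x numeric positions.
#' @return fitted values.
#' @export
predict_trajectory <- function(fit, x) {
  drop(outer(x, 0:fit$degree, `^`) %*% fit$coefficients)
}

#' Fit trajectories for every protein in a table
#'
#' By default fits the replicate means per condition (one point per
#' condition); `use_replicates = TRUE` fits all replicate points instead.
#' Conditions are coded as integers 0..6 in the order of
#' [condition_levels()]; `drop_reference = TRUE` removes the reference
#' condition before fitting.
#'
#' @param table an [abundance_table()] (normally after
#'   [normalize_to_reference()]).
#' @param degree polynomial degree.
#' @param use_replicates fit replicate points instead of condition means.
#' @param drop_reference drop the first condition (GL) from the abscissa.
#' @return data.frame with one row per protein: `protein`, `c0`..`c<degree>`,
#'   `r2`, `adj_r2`, `n`.
#' @export
fit_trajectories <- function(table, degree = 4, use_replicates = FALSE,
                             drop_reference = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  out <- lapply(split(as.data.frame(table), table$protein, drop = TRUE),
                function(d) {
    if (use_replicates) {
      x <- as.integer(d$condition) - 1; y <- d$abundance
    } else {
      m <- tapply(d$abundance, d$condition, mean)
      m <- m[!is.na(m)]
      x <- match(names(m), condition_levels()) - 1; y <- as.numeric(m)
    }
    if (drop_reference) { keep <- x != 0; x <- x[keep]; y <- y[keep] }
    ft <- fit_trajectory(x, y, degree)
    stats::setNames(
      data.frame(d$protein[1], t(ft$coefficients), ft$r2, ft$adj_r2, ft$n,
                 stringsAsFactors = FALSE),
      c("protein", paste0("c", 0:degree), "r2", "adj_r2", "n"))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Band-intensity table for native-gel quantification
#'
#' @param df data.frame with columns `assembly` (e.g. `"PSI trimer"`,
#'   `"PSI monomer"`, `"PSII dimer"`, `"PSII monomer"`, `"RC47"`),
#'   `condition`, `replicate`, `intensity` (>= 0).
#' @return validated data.frame of class `band_table`.
#' @export
band_table <- function(df) {
  need <- c("assembly", "condition", "replicate", "intensity")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$intensity < 0)) stop("band intensities must be non-negative")
  class(df) <- c("band_table", "data.frame")
  df
}

#' Oligomer/monomer ratios per condition
#'
#' For each requested pair the ratio numerator/denominator is computed per
#' replicate, then summarised as mean and sample SD per condition. Replicate
#' sets must match between the two assemblies of a pair. Zero-denominator
#' replicates (e.g. no trimer band detected early in biogenesis) make the
#' condition's entry undefined: the ratio is reported as `NA` and flagged,
#' never as a number.
#'
#' @param bands a [band_table()].
#' @param pairs named list of `c(numerator, denominator)` assembly pairs;
#'   default PSI monomer/trimer and PSII monomer/dimer.
#' @return data.frame: `pair`, `condition`, `mean_ratio`, `sd_ratio`,
#'   `n`, `undefined` (TRUE when any denominator replicate was zero).
#' @export
oligomer_ratios <- function(bands,
                            pairs = list(
                              "PSI monomer/trimer" = c("PSI monomer", "PSI trimer"),
                              "PSII monomer/dimer" = c("PSII monomer", "PSII dimer"))) {
  stopifnot(inherits(bands, "band_table"))
  rows <- list()
  for (pname in names(pairs)) {
    num_lab <- pairs[[pname]][1]; den_lab <- pairs[[pname]][2]
    for (cond in unique(bands$condition)) {
      num <- bands[bands$assembly == num_lab & bands$condition == cond, ]
      den <- bands[bands$assembly == den_lab & bands$condition == cond, ]
      if (nrow(num) == 0 || nrow(den) == 0) next
      num <- num[order(num$replicate), ]; den <- den[order(den$replicate), ]
      if (!identical(num$replicate, den$replicate))
        stop("mismatched replicate sets for ", pname, " in ", cond)
      if (any(den$intensity == 0)) {
        rows[[length(rows) + 1]] <- data.frame(
          pair = pname, condition = cond, mean_ratio = NA_real_,
          sd_ratio = NA_real_, n = nrow(num), undefined = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      r <- num$intensity / den$intensity
      rows[[length(rows) + 1]] <- data.frame(
        pair = pname, condition = cond, mean_ratio = mean(r),
        sd_ratio = if (length(r) > 1) stats::sd(r) else NA_real_,
        n = length(r), undefined = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
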