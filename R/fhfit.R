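#' @title Fitting interaction parameters to coexistence data
#' @name fhfit
#' @description
#' Reproduces the protocol in which an effective relative permittivity
#' `epsilon_r` (shared across systems) and per-sequence Flory-Huggins
#' components `(eps_h, eps_s)` are determined by fitting restricted-mode
#' binodals to measured dilute/dense coexistence concentrations. Residuals
#' are taken in log-concentration, weighting the dilute and dense arms
#' equally and making the objective invariant under concentration-unit
#' changes.
NULL

#' Read a coexistence dataset (TSV)
#'
#' Expected columns: `sequence` (label), `T_C` (temperature, Celsius; a
#' `T_K` column in kelvin is also accepted), `salt_M` (salt molarity),
#' `phase` (`dilute` or `dense`), `conc` and `unit` (`uM`, `mM`, `M`,
#' `mg/ml`, or `b-3`; mass units require the sequence to be resolvable for
#' its molar mass). Each (sequence, T, salt) pair may carry at most one
#' dilute and one dense row.
#'
#' @param path TSV file path.
#' @param sequences named list of `ResidueSequence` objects used to convert
#'   mass concentrations; defaults to the built-in fixtures.
#' @return a `CoexistenceDataset` data.frame with normalized columns
#'   `sequence`, `T_K`, `rho_s` (b^-3), `phase`, `rho_p` (chains b^-3) and
#'   the original `conc`/`unit`.
#' @export
load_coexistence <- function(path, sequences = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence", "salt_M", "phase", "conc", "unit")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"T_K" %in% names(df)) {
    if (!"T_C" %in% names(df)) stop("need a T_C or T_K column")
    df$T_K <- df$T_C + 273.15
  }
  bad <- which(!df$phase %in% c("dilute", "dense"))
  if (length(bad)) stop("malformed phase tag at data row(s): ",
                        paste(bad, collapse = ","))
  bad <- which(!is.finite(df$conc) | df$conc < 0)
  if (length(bad)) stop("malformed concentration at data row(s): ",
                        paste(bad, collapse = ","))
  key <- paste(df$sequence, df$T_K, df$salt_M, df$phase)
  if (anyDuplicated(key)) stop("duplicate phase row(s) at data row(s): ",
                               paste(which(duplicated(key)), collapse = ","))
  if (is.null(sequences)) {
    sequences <- lapply(setNames(nm = unique(df$sequence)), function(lab)
      tryCatch(builtin_sequence(lab), error = function(e) NULL))
  }
  df$rho_p <- vapply(seq_len(nrow(df)), function(i) {
    u <- df$unit[i]
    mm <- NULL
    if (u == "mg/ml") {
      sq <- sequences[[df$sequence[i]]]
      if (is.null(sq)) stop("mg/ml requires a known sequence: ", df$sequence[i])
      mm <- sequence_molar_mass(sq)
    }
    convert_conc(df$conc[i], u, "b-3", molar_mass = mm)
  }, numeric(1))
  df$rho_s <- convert_conc(df$salt_M, "M", "b-3")
  class(df) <- c("CoexistenceDataset", "data.frame")
  df
}

#' Write a coexistence dataset (TSV round trip)
#'
#' @param df a `CoexistenceDataset` (or compatible data.frame).
#' @param path output TSV path.
#' @export
write_coexistence <- function(df, path) {
  cols <- intersect(c("sequence", "T_C", "T_K", "salt_M", "phase",
                      "conc", "unit"), names(df))
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# predicted dilute/dense chain densities for one (T, salt); NA on no LLPS.
# Exact repeats hit the hash cache; otherwise the solve is seeded from the
# most recent solution at the same (T, salt) (continuation in parameter
# space), falling back to the full hull-seeded path.
.predict_binodal <- function(cs, params, T_K, rho_s, cache = NULL,
                             rp_range = c(2e-6, 4e-3)) {
  key <- if (!is.null(cache))
    sprintf("%s|%.6g|%.6g|%.6g|%.6g|%.6g", cs$name, params$epsilon_r,
            params$eps_h, params$eps_s, T_K, rho_s)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  seed_key <- sprintf("seed|%s|%.6g|%.6g", cs$name, T_K, rho_s)
  bp <- NULL
  if (!is.null(cache) && !is.null(cache[[seed_key]])) {
    bp <- .tangent_newton(cs, rho_s, T_K, params, cache[[seed_key]])
  }
  if (is.null(bp)) bp <- .binodal_point(cs, rho_s, T_K, params, rp_range,
                                        quick = TRUE)
  out <- if (is.null(bp)) c(NA_real_, NA_real_) else bp
  if (!is.null(cache)) {
    cache[[key]] <- out
    if (!is.null(bp)) cache[[seed_key]] <- bp
  }
  out
}

#' Fit (epsilon_r, eps_h, eps_s) to coexistence data
#'
#' Least squares over log dilute/dense concentrations by Nelder-Mead, with
#' binodal solves cached by parameter hash. One `(eps_h, eps_s)` pair is
#' fitted per sequence; `epsilon_r` is shared across all datasets when
#' `share_epsilon_r = TRUE` (the Fig.-1-style joint fit). Conditions where
#' the model predicts no LLPS incur a smooth penalty.
#'
#' @param datasets list of `CoexistenceDataset` objects (or one).
#' @param sequences named list mapping dataset sequence labels to
#'   `ChargeSequence` objects; defaults to built-ins.
#' @param start named start values `c(epsilon_r, eps_h, eps_s)`.
#' @param share_epsilon_r logical.
#' @param fix list of parameter names to hold at their start values (any of
#'   `"epsilon_r"`, `"eps_h"`, `"eps_s"`); useful for scaled-down fits.
#' @param v2 excluded-volume parameter (not fitted).
#' @param bounds list with elements `epsilon_r`, `eps_h`, `eps_s`, each
#'   `c(lo, hi)`.
#' @param control passed to [stats::optim()] (Nelder-Mead).
#' @param rp_range polymer-concentration search window for the binodal
#'   solves (b^-3); must bracket both arms of the data.
#' @return list with `epsilon_r`, per-sequence `eps_h`, `eps_s`, the final
#'   objective `value`, per-row `residuals`, and the optimizer `trace`.
#' @export
fit_parameters <- function(datasets, sequences = NULL,
                           start = c(epsilon_r = 80, eps_h = 1.2,
                                     eps_s = -0.5),
                           share_epsilon_r = TRUE, fix = character(),
                           v2 = 2.4,
                           bounds = list(epsilon_r = c(20, 120),
                                         eps_h = c(0, 5), eps_s = c(-5, 5)),
                           control = list(maxit = 200, reltol = 1e-8),
                           rp_range = c(2e-6, 4e-3)) {
  if (inherits(datasets, "CoexistenceDataset")) datasets <- list(datasets)
  data <- do.call(rbind, lapply(datasets, as.data.frame))
  labs <- unique(data$sequence)
  if (is.null(sequences))
    sequences <- lapply(setNames(nm = labs), function(l)
      charge_sequence(builtin_sequence(l)))
  for (l in labs) {
    nT <- length(unique(data$T_K[data$sequence == l]))
    if (nT < 2) stop("need >= 2 temperatures per dataset (", l, ")")
  }
  if (!share_epsilon_r && length(labs) > 1)
    stop("per-dataset epsilon_r: fit datasets separately")

  cache <- new.env(parent = emptyenv())
  # free parameters: epsilon_r (maybe) + (eps_h, eps_s) per sequence
  par_names <- c(if (!"epsilon_r" %in% fix) "epsilon_r",
                 unlist(lapply(labs, function(l)
                   paste0(c("eps_h.", "eps_s."), l))))
  par_names <- setdiff(par_names,
                       unlist(lapply(labs, function(l)
                         paste0(c("eps_h.", "eps_s.")[c("eps_h", "eps_s") %in% fix], l))))
  p0 <- vapply(par_names, function(nm) {
    base <- sub("\\..*$", "", nm)
    unname(start[[base]])
  }, numeric(1))
  names(p0) <- par_names

  unpack <- function(p) {
    er <- if ("epsilon_r" %in% names(p)) p[["epsilon_r"]] else start[["epsilon_r"]]
    out <- list(epsilon_r = er)
    for (l in labs) {
      eh <- if (paste0("eps_h.", l) %in% names(p)) p[[paste0("eps_h.", l)]] else start[["eps_h"]]
      es <- if (paste0("eps_s.", l) %in% names(p)) p[[paste0("eps_s.", l)]] else start[["eps_s"]]
      out[[l]] <- c(eps_h = eh, eps_s = es)
    }
    out
  }
  trace_env <- new.env(parent = emptyenv()); trace_env$tr <- list()

  objective <- function(p) {
    names(p) <- par_names
    pr <- unpack(p)
    # box penalty (Nelder-Mead is unconstrained)
    pen <- 0
    chk <- function(v, b) max(0, b[1] - v, v - b[2])
    pen <- pen + 100 * chk(pr$epsilon_r, bounds$epsilon_r)^2
    for (l in labs) {
      pen <- pen + 100 * (chk(pr[[l]]["eps_h"], bounds$eps_h)^2 +
                            chk(pr[[l]]["eps_s"], bounds$eps_s)^2)
    }
    if (pen > 0) return(1e4 + pen)
    ss <- 0
    for (l in labs) {
      cs <- sequences[[l]]
      prm <- energy_params(epsilon_r = pr$epsilon_r,
                           eps_h = pr[[l]][["eps_h"]],
                           eps_s = pr[[l]][["eps_s"]], v2 = v2)
      sub <- data[data$sequence == l, ]
      conds <- unique(sub[, c("T_K", "rho_s")])
      for (i in seq_len(nrow(conds))) {
        bp <- .predict_binodal(cs, prm, conds$T_K[i], conds$rho_s[i], cache,
                               rp_range)
        rows <- sub[sub$T_K == conds$T_K[i] & sub$rho_s == conds$rho_s[i], ]
        for (j in seq_len(nrow(rows))) {
          pred <- if (rows$phase[j] == "dilute") bp[1] else bp[2]
          ss <- ss + if (is.na(pred)) 25 else
            (log(pred) - log(rows$rho_p[j]))^2
        }
      }
    }
    trace_env$tr[[length(trace_env$tr) + 1]] <- c(p, value = ss)
    ss
  }
  opt <- if (length(p0) == 0) {
    list(par = p0, value = objective(p0), convergence = 0L)
  } else if (length(p0) == 1) {
    o <- stats::optim(p0, objective, method = "Brent",
                      lower = -10, upper = 130)
    o
  } else {
    stats::optim(p0, objective, method = "Nelder-Mead", control = control)
  }
  names(opt$par) <- par_names
  best <- unpack(opt$par)
  # residuals at the optimum
  resid <- do.call(rbind, lapply(labs, function(l) {
    cs <- sequences[[l]]
    prm <- energy_params(epsilon_r = best$epsilon_r,
                         eps_h = best[[l]][["eps_h"]],
                         eps_s = best[[l]][["eps_s"]], v2 = v2)
    sub <- data[data$sequence == l, ]
    sub$pred <- vapply(seq_len(nrow(sub)), function(j) {
      bp <- .predict_binodal(cs, prm, sub$T_K[j], sub$rho_s[j], cache,
                             rp_range)
      if (sub$phase[j] == "dilute") bp[1] else bp[2]
    }, numeric(1))
    sub$log_resid <- log(sub$pred) - log(sub$rho_p)
    sub
  }))
  structure(list(epsilon_r = best$epsilon_r,
                 per_sequence = best[labs],
                 value = opt$value, convergence = opt$convergence,
                 residuals = resid,
                 trace = do.call(rbind, trace_env$tr)),
            class = "fhfit")
}

#' @export
print.fhfit <- function(x, ...) {
  cat("rG-RPA+FH parameter fit\n")
  cat("  epsilon_r =", signif(x$epsilon_r, 4), "\n")
  for (l in names(x$per_sequence))
    cat(sprintf("  %s: eps_h = %.4g, eps_s = %.4g\n", l,
                x$per_sequence[[l]]["eps_h"], x$per_sequence[[l]]["eps_s"]))
  cat("  objective =", signif(x$value, 4), "\n")
  invisible(x)
}
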