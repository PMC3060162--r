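#' Canonical simulation scenarios
#'
#' Fully specified parameter sets for the systems studied throughout the
#' package:
#' * `"paper15"`: 15 species, growth rates geometrically spaced on
#'   \[0.1, 0.3\], equal fixpoint abundances `n0 = 100/15` per patch,
#'   `alpha0 = 0.001`.
#' * `"paper10"`, `"paper6"`: the analogous 10- and 6-species systems with
#'   `n0 = 100/N` (total 100 per patch, matching the 15-species system; the
#'   per-species split is an assumption recorded in the scenario).
#' * `"two_species_S1"`: a focal fast species `(mu, Y) = (0.5, 125)` at
#'   `alpha = 0.01` together with a slower, more efficient companion
#'   `(0.25, 200)` chosen from its coexistence region (the companion is a
#'   synthetic choice; the pair coexists at an interior fixpoint).
#'
#' @param name scenario id.
#' @param cv noise coefficient of variation (default 0.15).
#' @param cycles simulated cycles (default 1e5).
#' @param seed noise seed.
#' @return an object of class `scenario` (a named list).
#' @export
build_fixture <- function(name = c("paper15", "paper10", "paper6",
                                   "two_species_S1"),
                          cv = 0.15, cycles = 1e5, seed = 1L) {
  name <- match.arg(name)
  base <- list(name = name, cv = cv, cycles = cycles, seed = as.integer(seed),
               tail_epsilon = 1e-7, adaptive = TRUE, R = 1,
               clamp_regime = "full")
  s <- switch(name,
    paper15 = c(base, list(N = 15L, mu = mu_grid(15), n0 = 100 / 15,
                           alpha0 = 1e-3)),
    paper10 = c(base, list(N = 10L, mu = mu_grid(10), n0 = 100 / 10,
                           alpha0 = 1e-3)),
    paper6 = c(base, list(N = 6L, mu = mu_grid(6), n0 = 100 / 6,
                          alpha0 = 1e-3)),
    two_species_S1 = c(base, list(N = 2L, mu = c(0.25, 0.5),
                                  Y = c(200, 125), alpha0 = 0.01)))
  structure(s, class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': N = %d, alpha0 = %g, cv = %g, cycles = %g\n",
              x$name, x$N, x$alpha0, x$cv, x$cycles))
  invisible(x)
}

#' Serialize a scenario to a flat key-value file
#'
#' Human-readable, diffable `key = value` lines; numeric vectors are
#' comma-joined at full precision. [read_scenario()] restores an identical
#' object.
#'
#' @param s a `scenario`.
#' @param file output path.
#' @export
write_scenario <- function(s, file) {
  stopifnot(inherits(s, "scenario"))
  fmt <- function(v) {
    if (is.character(v)) return(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = ",")
  }
  lines <- vapply(names(s), function(k) sprintf("%s = %s", k, fmt(s[[k]])), "")
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(file) {
  lines <- readLines(file)
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, " = ", fixed = TRUE)[[1]]
    key <- kv[1]
    val <- kv[2]
    parsed <- suppressWarnings(as.numeric(strsplit(val, ",", fixed = TRUE)[[1]]))
    if (any(is.na(parsed))) parsed <- if (val %in% c("TRUE", "FALSE")) as.logical(val) else val
    if (key %in% c("N", "seed", "cycles")) parsed <- as.integer(parsed)
    if (key == "adaptive") parsed <- as.logical(val)
    out[[key]] <- parsed
  }
  out$cycles <- as.numeric(out$cycles)
  structure(out, class = "scenario")
}

scenario_hash <- function(s) {
  txt <- paste(vapply(names(s), function(k)
    paste(k, paste(format(s[[k]], digits = 17), collapse = ","), sep = "="), ""),
    collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31   # djb2, kept in integer range
  sprintf("%08x", h)
}

#' Run a scenario end to end
#'
#' Executes the full pipeline for a [build_fixture()] scenario: solve the
#' equal-abundance efficiencies (unless the scenario fixes `Y`
#' explicitly), linearize around the fixpoint, simulate `cycles` noisy
#' cycles, and summarise (correlation curve and empirical mode
#' amplitudes). With `cycles = 0` only the fixpoint and linear model are
#' produced. When `out_dir` is given, fixpoint, mode table, `J`/`r`
#' matrices, trace, correlation curve and a provenance log (scenario hash,
#' seed, truncation metadata) are written as delimited text.
#'
#' @param s a `scenario`.
#' @param out_dir optional output directory.
#' @return list with `fixpoint`, `linear`, and (when simulated) `trace`,
#'   `correlation`, `amplitudes`.
#' @export
run_experiment <- function(s, out_dir = NULL) {
  stopifnot(inherits(s, "scenario"))
  nm <- noise_model(s$cv, s$alpha0)
  if (!is.null(s$Y)) {
    comm <- community(s$mu, s$Y, R = s$R)
    n_star <- fixpoint_by_iteration(comm, s$alpha0)
    fp <- structure(list(community = comm, n_star = n_star,
                         alpha0 = s$alpha0, residual = NA_real_,
                         converged = TRUE, iterations = NA_integer_,
                         M = NA_integer_, tail_epsilon = 1e-13),
                    class = "fixpoint_result")
  } else {
    fp <- solve_efficiencies(s$n0, s$mu, s$alpha0, R = s$R)
  }
  lm <- linearize(fp, sigma_alpha = nm$sigma_alpha)
  out <- list(scenario = s, fixpoint = fp, linear = lm)
  if (s$cycles > 0) {
    pol <- truncation_policy(tail_epsilon = s$tail_epsilon,
                             adaptive = s$adaptive,
                             static_M = if (s$adaptive) NULL else
                               derive_truncation(fp$n_star, s$alpha0,
                                                 s$tail_epsilon))
    tr <- simulate_trace(fp, nm, cycles = s$cycles, seed = s$seed,
                         policy = pol)
    burn <- min(1000L, floor(s$cycles / 10))
    out$trace <- tr
    out$correlation <- correlation_vs_distance(tr, "full", burn_in = burn)
    out$amplitudes <- empirical_mode_amplitudes(tr, lm, burn_in = burn)
  }
  if (!is.null(out_dir)) export_bundle(out, out_dir)
  invisible(out)
}

# deterministic fixpoint location for explicit-Y communities: iterate the
# expectation map to a fixed tolerance
fixpoint_by_iteration <- function(comm, alpha, init = NULL, tol = 1e-10,
                                  max_iter = 2e5) {
  n <- if (is.null(init)) rep(10, comm$N) else init
  cache <- seeding_cache(comm, derive_truncation(n, alpha, 1e-13))
  pol <- truncation_policy(tail_epsilon = 1e-13)
  for (i in seq_len(max_iter)) {
    n2 <- step_map(n, alpha, policy = pol, table = cache_at_least(
      cache, derive_truncation(n, alpha, 1e-13)))
    if (max(abs(n2 - n)) < tol * max(n2)) return(drop(n2))
    n <- drop(n2)
  }
  warning("fixpoint iteration did not reach tolerance")
  drop(n)
}

export_bundle <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- scenario_hash(out$scenario)
  stamp <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(sprintf("# scenario=%s hash=%s", out$scenario$name, h), con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  fp <- out$fixpoint
  stamp(data.frame(mu = fp$community$mu, Y = fp$community$Y,
                   n_star = fp$n_star), "fixpoint.tsv")
  stamp(mode_table(out$linear), "modes.tsv")
  stamp(as.data.frame(out$linear$J), "J.tsv")
  stamp(data.frame(r = out$linear$r), "r.tsv")
  if (!is.null(out$trace)) {
    write_trace(out$trace, file.path(out_dir, "trace.tsv"))
    stamp(out$correlation$pairs, "correlation.tsv")
    stamp(out$amplitudes, "amplitudes.tsv")
  }
  tmp <- tempfile()
  write_scenario(out$scenario, tmp)
  writeLines(c(sprintf("hash = %s", h),
               sprintf("mc_fallbacks = %s",
                       if (is.null(out$trace)) 0 else
                         out$trace$metadata$mc_fallbacks),
               readLines(tmp)),
             file.path(out_dir, "provenance.txt"))
  unlink(tmp)
  invisible(out_dir)
}
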