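#' Shared growth-outcome cache for repeated simulations
#'
#' A mutable wrapper around a [seeding_table()] that grows on demand and is
#' shared by reference, so a batch of simulations (e.g. the N^2 pairwise
#' clamp runs) never re-solves a growth outcome twice.
#'
#' @param comm a [community()].
#' @param max_total initial table bound.
#' @return an environment of class `seeding_cache` holding `$table`.
#' @export
seeding_cache <- function(comm, max_total = 6L) {
  e <- new.env(parent = emptyenv())
  e$table <- seeding_table(comm, max_total)
  class(e) <- "seeding_cache"
  e
}

cache_at_least <- function(cache, max_total) {
  if (cache$table$max_total < max_total)
    cache$table <- extend_seeding_table(cache$table, max_total)
  cache$table
}

#' Simulate the stochastic patch dynamics
#'
#' Iterates the expectation update under a per-cycle random dilution factor.
#' Each cycle draws (or takes) an `alpha`, applies the truncated expectation
#' update, then overwrites any clamped species with their fixpoint
#' abundances (clamped species keep exerting competitive pressure at
#' `n_star`, the clamp being re-imposed after the growth/dispersal update).
#'
#' @param fp a [solve_efficiencies()] result.
#' @param nm a [noise_model()]; ignored when `alphas` is supplied.
#' @param cycles number of cycles to simulate.
#' @param clamp logical vector: species held at their fixpoint abundance.
#' @param init initial abundances (default: the fixpoint).
#' @param policy a [truncation_policy()].
#' @param seed integer seed used to draw the `alpha` series (same seed =
#'   bitwise identical series across clamp configurations).
#' @param alphas optional explicit dilution series (overrides `nm`/`seed`).
#' @param cache optional [seeding_cache()] shared across runs.
#' @return An object of class `sim_trace`: `abundances` (cycles x N
#'   matrix), `alphas`, `clamp`, `n_star`, `z` and `metadata` (seed,
#'   policy, per-cycle truncation total `M`, enumerated mass, Monte-Carlo
#'   flags).
#' @export
simulate_trace <- function(fp, nm = NULL, cycles, clamp = NULL, init = NULL,
                           policy = truncation_policy(), seed = NULL,
                           alphas = NULL, cache = NULL) {
  stopifnot(inherits(fp, "fixpoint_result"))
  comm <- fp$community
  N <- comm$N
  if (is.null(alphas)) {
    stopifnot(inherits(nm, "noise_model"))
    alphas <- draw_alphas(nm, cycles, seed = seed)
  }
  if (length(alphas) != cycles) stop("'alphas' must have length 'cycles'")
  if (is.null(clamp)) clamp <- rep(FALSE, N)
  if (length(clamp) != N) stop("'clamp' must have one entry per species")
  if (is.null(init)) init <- fp$n_star
  if (length(init) != N || any(init < 0)) stop("invalid initial abundances")

  adaptive <- policy$adaptive
  static_M <- if (adaptive) -1L else policy$static_M
  M0 <- max(derive_truncation(init, max(alphas[1], fp$alpha0),
                              policy$tail_epsilon),
            if (!adaptive) static_M else 0L, 1L)
  if (is.null(cache)) cache <- seeding_cache(comm, M0)
  tab <- cache_at_least(cache, M0)

  abund <- matrix(NA_real_, cycles, N)
  Mused <- integer(cycles)
  mass <- numeric(cycles)
  mc <- logical(cycles)
  n_cur <- init
  done <- 0L
  while (done < cycles) {
    idx <- (done + 1L):cycles
    res <- sim_loop_cpp(tab$mm, tab$Fm, tab$lfac, tab$cumrows, n_cur,
                        fp$n_star, clamp, alphas[idx], policy$tail_epsilon,
                        adaptive, static_M, policy$config_ceiling,
                        policy$mc_samples, comm$mu, comm$Y, comm$R)
    ran <- res$stop_cycle           # cycles completed within this segment
    if (ran > 0) {
      seg <- idx[seq_len(ran)]
      abund[seg, ] <- res$abund[seq_len(ran), , drop = FALSE]
      Mused[seg] <- res$M[seq_len(ran)]
      mass[seg] <- res$mass[seq_len(ran)]
      mc[seg] <- res$mc[seq_len(ran)]
    }
    n_cur <- res$n_current
    done <- done + ran
    if (res$status == 2L)
      stop(sprintf(paste0("abundances became non-finite at cycle %d ",
                          "(excursion beyond model validity)"), done + 1L))
    if (res$status == 1L)
      tab <- cache_at_least(cache, res$need_M + 2L)
  }
  structure(
    list(abundances = abund, alphas = alphas, clamp = clamp,
         n_star = fp$n_star, z = comm$z, community = comm,
         metadata = list(seed = seed, cycles = cycles,
                         tail_epsilon = policy$tail_epsilon,
                         adaptive = adaptive, static_M = static_M,
                         M = Mused, mass = mass, mc = mc,
                         mc_fallbacks = sum(mc))),
    class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf(
    "sim_trace: %d cycles, %d species (%d clamped), %d Monte-Carlo fallbacks\n",
    nrow(x$abundances), ncol(x$abundances), sum(x$clamp),
    x$metadata$mc_fallbacks))
  invisible(x)
}

#' Deterministic perturbation experiments around the fixpoint
#'
#' Runs the noiseless dynamics from the fixpoint and applies a single
#' perturbation: a one-cycle spike in `alpha` (`"alpha_pulse"`), a permanent
#' shift in `alpha` from `at_cycle` onward (`"alpha_press"`), or an
#' instantaneous addition to one species' abundance (`"species_pulse"`).
#'
#' @param fp a [solve_efficiencies()] result.
#' @param kind perturbation type.
#' @param magnitude size of the perturbation: an additive change in `alpha`
#'   for the alpha kinds, an additive abundance change for the species
#'   pulse.
#' @param at_cycle cycle at which the perturbation is applied.
#' @param cycles total cycles simulated.
#' @param species index of the perturbed species (`"species_pulse"` only).
#' @param policy a [truncation_policy()].
#' @param cache optional [seeding_cache()].
#' @return a [simulate_trace()] result (deterministic).
#' @export
perturbation_experiment <- function(fp,
                                    kind = c("alpha_pulse", "species_pulse",
                                             "alpha_press"),
                                    magnitude, at_cycle, cycles,
                                    species = NULL,
                                    policy = truncation_policy(),
                                    cache = NULL) {
  kind <- match.arg(kind)
  if (at_cycle < 1 || at_cycle > cycles) stop("'at_cycle' out of range")
  alphas <- rep(fp$alpha0, cycles)
  if (kind == "alpha_pulse") alphas[at_cycle] <- fp$alpha0 + magnitude
  if (kind == "alpha_press") alphas[at_cycle:cycles] <- fp$alpha0 + magnitude
  if (kind != "species_pulse")
    return(simulate_trace(fp, cycles = cycles, alphas = alphas,
                          policy = policy, cache = cache))
  if (is.null(species) || species < 1 || species > fp$community$N)
    stop("'species' must index a species for a species pulse")
  first <- simulate_trace(fp, cycles = at_cycle, alphas = alphas[1:at_cycle],
                          policy = policy, cache = cache)
  n_kick <- first$abundances[at_cycle, ]
  n_kick[species] <- n_kick[species] + magnitude
  if (at_cycle == cycles) {
    first$abundances[at_cycle, ] <- n_kick
    return(first)
  }
  rest <- simulate_trace(fp, cycles = cycles - at_cycle, init = n_kick,
                         alphas = alphas[(at_cycle + 1):cycles],
                         policy = policy, cache = cache)
  first$abundances[at_cycle, ] <- n_kick
  out <- first
  out$abundances <- rbind(first$abundances, rest$abundances)
  out$alphas <- alphas
  out$metadata$cycles <- cycles
  out$metadata$M <- c(first$metadata$M, rest$metadata$M)
  out$metadata$mass <- c(first$metadata$mass, rest$metadata$mass)
  out$metadata$mc <- c(first$metadata$mc, rest$metadata$mc)
  out$metadata$mc_fallbacks <- sum(out$metadata$mc)
  out
}

#' Write a simulation trace to disk
#'
#' Long-format delimited text (`cycle`, `alpha`, `species`, `abundance`)
#' with a commented metadata header, or a compact `.rds` container holding
#' the full trace object.
#'
#' @param trace a `sim_trace`.
#' @param file output path.
#' @param format `"tsv"` or `"rds"`.
#' @export
write_trace <- function(trace, file, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(trace, file)
    return(invisible(file))
  }
  con <- file(file, "w")
  on.exit(close(con))
  md <- trace$metadata
  writeLines(sprintf("# cycles=%d seed=%s tail_epsilon=%g adaptive=%s mc_fallbacks=%d",
                     md$cycles, ifelse(is.null(md$seed), "NA", md$seed),
                     md$tail_epsilon, md$adaptive, md$mc_fallbacks), con)
  N <- ncol(trace$abundances)
  cycles <- nrow(trace$abundances)
  df <- data.frame(cycle = rep(seq_len(cycles), each = N),
                   alpha = rep(trace$alphas, each = N),
                   species = rep(seq_len(N), cycles),
                   abundance = as.vector(t(trace$abundances)))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
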