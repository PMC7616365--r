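#' Model specification for fitting
#'
#' Bundles the free-parameter bounds with a builder that assembles a
#' parameter set and drift map from a named parameter vector. Built-in
#' helpers cover the four experiment templates; custom builders allow any
#' parameterization.
#'
#' @param free named list of length-2 numeric bounds `c(lower, upper)`,
#'   one per free parameter (the optimization space).
#' @param log_scale names of free parameters searched on a log10 scale
#'   (sensible for rate parameters spanning decades, such as the leak);
#'   bounds are given on the natural scale and results are reported on
#'   it.
#' @param build `function(theta)` (named numeric vector) returning
#'   `list(params = <gcdf_params>, map = <gcdf_drift_map>)`. It may signal
#'   an error for infeasible combinations; [fit_model()] converts those
#'   into a constraint penalty.
#' @param label short description.
#' @return an object of class `gcdf_model_spec` with `m` (number of free
#'   parameters) computed from `free`.
#' @export
gcdf_model_spec <- function(free, build, label = "custom",
                            log_scale = character()) {
  stopifnot(is.list(free), length(free) >= 1, !is.null(names(free)),
            all(vapply(free, length, 1L) == 2), is.function(build),
            all(log_scale %in% names(free)))
  for (nm in log_scale)
    if (free[[nm]][1] <= 0)
      stop("log-scale parameter `", nm, "` needs positive bounds")
  structure(list(free = free, build = build, m = length(free),
                 label = label, log_scale = log_scale),
            class = "gcdf_model_spec")
}

#' Model specification for the linear-coherence design
#'
#' Raw variants free the slope `k`, gate `g`, threshold `r`, residual
#' latencies `Te`, `Tr` (plus the leak `lambda` for the filtered model);
#' full variants add the between-trial variability terms. Bounds are
#' broad, physiologically sensible defaults and can be overridden.
#'
#' @param variant `"GCDF"` or `"GCD"`.
#' @param raw if `TRUE` (default) no between-trial variability parameters.
#' @param bounds optional named list overriding individual default bounds.
#' @return a [gcdf_model_spec()].
#' @export
spec_linear_coherence <- function(variant = c("GCDF", "GCD"), raw = TRUE,
                                  bounds = list()) {
  variant <- match.arg(variant)
  free <- list(k = c(0.1, 4), g = c(0.005, 0.25), r = c(0.002, 0.15),
               Te = c(0.05, 0.8), Tr = c(0.02, 0.4))
  if (variant == "GCDF") free$lambda <- c(2, 200)
  if (!raw) {
    free <- c(free, list(sv = c(0, 0.6), sx0 = c(0, 0.3),
                         sTe = c(0, 0.6), sTr = c(0, 0.4)))
    if (variant == "GCDF") free$slambda <- c(0, 200)
  }
  free[names(bounds)] <- bounds
  build <- function(theta) {
    th <- as.list(theta)
    p <- gcdf_params(variant = variant, g = th$g, r = th$r,
                     Te = th$Te, Tr = th$Tr, x0 = 0,
                     lambda = th$lambda,
                     sv = th$sv %||% 0, sx0 = th$sx0 %||% 0,
                     sTe = th$sTe %||% 0, sTr = th$sTr %||% 0,
                     slambda = th$slambda %||% 0)
    list(params = p, map = drift_linear(th$k))
  }
  gcdf_model_spec(free, build,
                  label = sprintf("%s linear-coherence (%s)", variant,
                                  if (raw) "raw" else "full"),
                  log_scale = intersect("lambda", names(free)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tighten residual-latency bounds from the observed data
#'
#' In a model without between-trial variability in the residual
#' latencies, every premotor time satisfies `PMT >= Te` and every motor
#' time `MT >= Tr`, so the observed minima are valid upper bounds for
#' those parameters. Applying them shrinks the search space of a raw-model
#' fit — a mathematical implication of the model, not a heuristic. With
#' variability the bounds apply to `Te - sTe/2` (resp. `Tr - sTr/2`) and
#' are widened by `slack` times the observed minimum instead.
#'
#' @param spec a [gcdf_model_spec()] with free `Te` and/or `Tr`.
#' @param observed the observed trial table the fit will target.
#' @param raw whether the spec has no `sTe`/`sTr` variability (exact
#'   bounds); otherwise the bounds are widened by `slack`.
#' @param slack multiplicative widening for variability-bearing specs.
#' @return the spec with tightened upper bounds.
#' @export
tighten_bounds_from_data <- function(spec, observed, raw = TRUE,
                                     slack = 0.9) {
  stopifnot(inherits(spec, "gcdf_model_spec"))
  live <- observed[!observed$omitted, , drop = FALSE]
  f <- if (raw) 1 else 1 / slack
  if ("Te" %in% names(spec$free)) {
    cap <- f * min(live$pmt)
    spec$free$Te[2] <- max(spec$free$Te[1] * 1.5,
                           min(spec$free$Te[2], cap))
  }
  if ("Tr" %in% names(spec$free)) {
    cap <- f * min(live$mt)
    spec$free$Tr[2] <- max(spec$free$Tr[1] * 1.5,
                           min(spec$free$Tr[2], cap))
  }
  spec
}

#' Fit a model to an observed trial table by simulation
#'
#' Minimizes the quantile-binned G-squared statistic over the free
#' parameters by differential evolution. Each candidate is evaluated by
#' simulating `n_sim` trials per condition with a fixed evaluation seed
#' (common random numbers: every candidate reuses the same frozen
#' per-trial-index noise streams, making the objective a deterministic
#' function of the parameters), binning against the observed boundaries,
#' and computing G-squared. Candidates violating the parameter
#' constraints (nonnegativity, 180% caps) receive the objective plus a
#' large penalty rather than being reparameterized. Repeated runs with
#' the same master seed are identical.
#'
#' @param observed observed trial table (with the design's conditions).
#' @param spec a [gcdf_model_spec()].
#' @param design the experiment design ([make_design()]); its
#'   per-condition `n_trials` are replaced by `n_sim` for simulation.
#' @param n_sim simulated trials per condition per evaluation
#'   (20000 reproduces the reference fit budget; smaller values trade
#'   objective noise for speed).
#' @param n_pop DE population size (default `10 * m`).
#' @param n_gen DE generations.
#' @param CR crossover probability.
#' @param F_range mutation factor, dithered per candidate in this range.
#' @param strategy DE mutation strategy: `"randtobest1bin"` (default;
#'   pulls mutants toward the incumbent best while keeping population
#'   diversity — suited to the moderate evaluation budgets a
#'   simulation-based objective allows), `"best1bin"`, or the classic
#'   `"rand1bin"`.
#' @param explore optional exploration schedule run before the main
#'   phase: either one `list(n_sim =, n_gen =)` or a list of such
#'   phases in increasing `n_sim` order. Each phase runs the same DE at
#'   a smaller simulation budget and hands its final population to the
#'   next, so cheap generations do the broad search while the reported
#'   parameters and G-squared always come from the full `n_sim`
#'   objective.
#' @param polish deterministic compass-search refinement at the full
#'   simulation budget after DE: coordinate probes with shrinking
#'   relative steps, pattern (diagonal) moves, and step-cycle restarts
#'   while probes keep paying off. `TRUE` (default, 80 probes at 6%
#'   initial step), `FALSE`, or `list(n_eval =, step =)`.
#' @param seed master seed controlling the optimizer and the evaluation
#'   seed.
#' @param config a [sim_config()].
#' @param bins optional pre-built [build_bins()] boundaries (defaults to
#'   boundaries from `observed`).
#' @param trace print per-generation progress.
#' @return an object of class `gcdf_fit`: list with `par` (best
#'   parameters), `g2`, `m`, `N`, `AIC`, `BIC`, `trace` (best per
#'   generation), `seeds`, `bins`, `n_eval`.
#' @export
fit_model <- function(observed, spec, design, n_sim = 20000,
                      n_pop = NULL, n_gen = 40, CR = 0.6,
                      F_range = c(0.6, 0.6),
                      strategy = c("randtobest1bin", "best1bin", "rand1bin"),
                      explore = NULL, polish = TRUE, seed = NULL,
                      config = sim_config(), bins = NULL, trace = FALSE) {
  stopifnot(inherits(spec, "gcdf_model_spec"))
  strategy <- match.arg(strategy)
  missing_conds <- setdiff(as.character(design$condition),
                           as.character(unique(observed$condition)))
  if (length(missing_conds))
    stop("observed table is missing design condition(s): ",
         paste(missing_conds, collapse = ", "))
  if (n_sim <= 0 || n_gen <= 0) stop("simulation/optimization budget must be > 0")
  if (!is.null(seed)) set.seed(seed)
  eval_seed <- sample.int(.Machine$integer.max, 1)

  if (is.null(bins)) bins <- build_bins(observed)
  obs_counts <- bin_counts(observed, bins)
  N <- sum(obs_counts$n_i)

  # optimization happens in search space: log10 for log-scale parameters
  is_log <- names(spec$free) %in% (spec$log_scale %||% character())
  from_search <- function(x) { x[is_log] <- 10^x[is_log]; x }
  to_search <- function(x) { x[is_log] <- log10(x[is_log]); x }
  lower <- to_search(vapply(spec$free, `[`, numeric(1), 1))
  upper <- to_search(vapply(spec$free, `[`, numeric(1), 2))
  d <- spec$m
  if (is.null(n_pop)) n_pop <- 10L * d
  PENALTY <- 1e6

  n_eval <- 0L
  # fixed per-condition evaluation seeds: common random numbers across
  # every candidate evaluation
  set.seed(eval_seed)
  cond_seeds <- sample.int(.Machine$integer.max, nrow(design))
  # G-squared is a sum of nonnegative per-condition divergences, so a
  # challenger can be abandoned exactly once its partial sum exceeds the
  # fitness it must beat ("racing"); cheap (fast-RT) conditions are
  # simulated first to make early abandonment likely
  obs_live <- observed[!observed$omitted, , drop = FALSE]
  cond_cost <- vapply(seq_len(nrow(design)), function(i)
    mean(obs_live$rt[obs_live$condition == design$condition[i]],
         na.rm = TRUE), numeric(1))
  cond_order <- order(cond_cost)
  cond_designs <- lapply(seq_len(nrow(design)), function(i)
    structure(design[i, , drop = FALSE],
              deadline = attr(design, "deadline", exact = TRUE),
              class = class(design)))
  obs_slices <- lapply(seq_len(nrow(design)), function(i)
    obs_counts$counts[i, , , ])

  g2_condition <- function(sim_tab, ci) {
    ns <- bin_counts(sim_tab, bins)$counts[ci, , , ]
    nsum <- sum(ns)
    n <- obs_slices[[ci]]
    p <- n / obs_counts$n_i[ci]
    q <- ns / nsum
    pos <- n > 0
    q[pos & q == 0] <- 1 / (2 * nsum)
    2 * sum(n[pos] * log(p[pos] / q[pos]))
  }

  make_objective <- function(n_sim_i) {
    function(theta, bound = Inf) {
      theta <- from_search(theta)
      names(theta) <- names(spec$free)
      built <- tryCatch(spec$build(theta), error = function(e) e)
      if (inherits(built, "error")) return(PENALTY)
      n_eval <<- n_eval + 1L
      rng_state <- .Random.seed
      g2 <- 0
      for (ci in cond_order) {
        di <- cond_designs[[ci]]
        di$n_trials <- n_sim_i
        sim <- simulate_dataset(built$params, built$map, di, config,
                                seed = cond_seeds[ci])
        if (all(sim$omitted)) { g2 <- g2 + PENALTY; break }
        g2 <- g2 + g2_condition(sim, ci)
        if (g2 > bound) break
      }
      assign(".Random.seed", rng_state, envir = globalenv())
      g2
    }
  }

  # differential evolution with binomial crossover and dithered F;
  # best/1/bin mutates around the incumbent best, rand/1/bin around a
  # random base vector
  de_phase <- function(pop, objective, n_gen_i, label) {
    fitness <- apply(pop, 1, objective)
    tr <- numeric(n_gen_i)
    for (gen in seq_len(n_gen_i)) {
      base_i <- which.min(fitness)
      for (i in seq_len(n_pop)) {
        idx <- sample(seq_len(n_pop)[-i], 3)
        Fi <- stats::runif(1, F_range[1], F_range[2])
        mutant <- switch(strategy,
          randtobest1bin = pop[idx[3], ] +
            Fi * (pop[base_i, ] - pop[idx[3], ]) +
            Fi * (pop[idx[1], ] - pop[idx[2], ]),
          best1bin = pop[base_i, ] + Fi * (pop[idx[1], ] - pop[idx[2], ]),
          rand1bin = pop[idx[3], ] + Fi * (pop[idx[1], ] - pop[idx[2], ]))
        mutant <- pmin(pmax(mutant, lower), upper)
        jrand <- sample.int(d, 1)
        cross <- stats::runif(d) < CR
        cross[jrand] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        f <- objective(trial, bound = fitness[i])
        if (f <= fitness[i]) { pop[i, ] <- trial; fitness[i] <- f }
      }
      tr[gen] <- min(fitness)
      if (trace) message(sprintf("%s gen %3d  best G2 = %.3f",
                                 label, gen, min(fitness)))
    }
    list(pop = pop, fitness = fitness, trace = tr)
  }

  pop <- matrix(stats::runif(n_pop * d, lower, upper),
                nrow = n_pop, ncol = d, byrow = TRUE)
  explore_trace <- numeric(0)
  if (!is.null(explore)) {
    phases <- if (!is.null(explore$n_sim)) list(explore) else explore
    for (ph in seq_along(phases)) {
      res <- de_phase(pop, make_objective(phases[[ph]]$n_sim %||% 1000),
                      phases[[ph]]$n_gen %||% n_gen,
                      sprintf("explore %d", ph))
      pop <- res$pop
      explore_trace <- c(explore_trace, res$trace)
    }
  }
  obj_main <- make_objective(n_sim)
  ph2 <- de_phase(pop, obj_main, n_gen, "main")
  best_trace <- ph2$trace
  best <- which.min(ph2$fitness)
  par <- ph2$pop[best, ]
  names(par) <- names(spec$free)
  g2 <- ph2$fitness[best]

  # deterministic compass-search polish at the full simulation budget:
  # coordinate probes with shrinking relative steps, racing against the
  # incumbent, removing residual optimizer variance at the basin bottom
  if (!identical(polish, FALSE)) {
    pol <- if (isTRUE(polish)) list() else polish
    budget <- pol$n_eval %||% 80
    s0 <- pol$step %||% 0.06
    s <- s0
    rng <- upper - lower
    clip <- function(x) pmin(pmax(x, lower), upper)
    cycle_gain <- 0
    g2_cycle <- g2
    while (budget > 0) {
      if (s < 0.005) {
        # restart the step cycle while budget remains, but stop once a
        # whole cycle no longer pays for itself
        cycle_gain <- g2_cycle - g2
        if (cycle_gain < 0.25) break
        g2_cycle <- g2
        s <- s0
      }
      sweep_start <- par
      improved <- FALSE
      for (j in seq_len(d)) {
        for (dir in c(1, -1)) {
          if (budget <= 0) break
          cand <- par
          cand[j] <- min(max(par[j] + dir * s * rng[j], lower[j]), upper[j])
          if (cand[j] == par[j]) next
          f <- obj_main(cand, bound = g2)
          budget <- budget - 1
          if (f < g2) {
            par <- cand
            g2 <- f
            improved <- TRUE
            if (trace) message(sprintf("polish  best G2 = %.3f (step %.3f)",
                                       g2, s))
            break
          }
        }
      }
      # pattern move: extrapolate the whole successful sweep (follows
      # diagonal trade-off ridges that axis probes cannot)
      if (improved && budget > 0 && any(par != sweep_start)) {
        cand <- clip(par + (par - sweep_start))
        if (any(cand != par)) {
          f <- obj_main(cand, bound = g2)
          budget <- budget - 1
          if (f < g2) {
            par <- cand
            g2 <- f
            if (trace) message(sprintf("polish  best G2 = %.3f (pattern)",
                                       g2))
          }
        }
      }
      if (!improved) s <- s / 2
    }
  }
  par <- from_search(par)
  ic <- information_criteria(g2, spec$m, N)
  structure(list(par = par, g2 = g2, m = spec$m, N = N,
                 AIC = unname(ic["AIC"]), BIC = unname(ic["BIC"]),
                 trace = best_trace, explore_trace = explore_trace,
                 n_eval = n_eval,
                 seeds = list(master = seed, eval = eval_seed),
                 bins = bins, spec_label = spec$label),
            class = "gcdf_fit")
}

#' @export
print.gcdf_fit <- function(x, ...) {
  cat("<gcdf_fit>", x$spec_label, "\n")
  cat(sprintf("  G2 = %.3f  AIC = %.3f  BIC = %.3f  (m = %d, N = %d)\n",
              x$g2, x$AIC, x$BIC, x$m, x$N))
  print(round(x$par, 4))
  invisible(x)
}
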