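#' Virtual-population specification
#'
#' Virtual individuals are generated by perturbing a fixed list of
#' drug-specific parameters -- hepatic intrinsic clearances (every pathway),
#' renal intrinsic clearance, unbound fraction in blood, systemic volume,
#' absorption parameter (Peff or ka) and the three tissue partition
#' coefficients -- each with an independent uniform multiplier, by default
#' on 80-120% of the base value.  Metabolite records are perturbed with
#' their own independent draws.
#'
#' @param n number of virtual individuals (default 1000).
#' @param low,high multiplier bounds (defaults 0.8 and 1.2).
#' @param seed integer seed; each individual uses a deterministic substream
#'   derived from `(seed, index)`, so populations are order-independent and
#'   reproducible.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n = 1000, low = 0.8, high = 1.2, seed = 1) {
  stopifnot(n >= 1, low > 0, low <= high)
  structure(list(n = as.integer(n), low = low, high = high,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# Deterministic per-individual uniform draws, isolated from the global RNG
# stream.  Counter-based: the substream seed depends only on (seed, index).
individual_draws <- function(spec, index, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  sub <- (as.double(spec$seed) * 48271 + as.double(index) * 16807) %%
    2147483587
  set.seed(as.integer(sub))
  stats::runif(k, spec$low, spec$high)
}

# The perturbable parameters of one record, in a fixed order.
perturb_record <- function(record, draws) {
  i <- 0L
  take <- function() { i <<- i + 1L; draws[i] }
  for (j in seq_along(record$pathways)) {
    pw <- record$pathways[[j]]
    if (pw$kind == "linear") pw$clint <- pw$clint * take()
    else pw$vmax <- pw$vmax * take()
    record$pathways[[j]] <- pw
  }
  if (!is.null(record$clint_k)) record$clint_k <- record$clint_k * take()
  record$fu_b <- min(1, record$fu_b * take())
  record$v_sys <- record$v_sys * take()
  if (!is.null(record$peff)) record$peff <- record$peff * take()
  if (!is.null(record$ka)) record$ka <- record$ka * take()
  record$k_lp <- record$k_lp * take()
  record$k_gp <- record$k_gp * take()
  record$k_kp <- record$k_kp * take()
  attr(record, "n_draws") <- i
  record
}

n_perturbable <- function(record) {
  length(record$pathways) +
    (!is.null(record$clint_k)) + 2L +
    (!is.null(record$peff)) + (!is.null(record$ka)) + 3L
}

#' Draw one virtual individual
#'
#' @param drug base [drug_record()] (already cirrhosis-translated when
#'   simulating patients).
#' @param spec a [population_spec()].
#' @param index individual index in 1..n.
#' @param metabolite optional metabolite record, perturbed with its own
#'   draws from the same substream.
#' @return list with perturbed `drug` and `metabolite` records and the
#'   `multipliers` used.
#' @export
sample_individual <- function(drug, spec, index, metabolite = NULL) {
  if (inherits(drug, "translated_parameters")) drug <- drug$drug
  if (inherits(metabolite, "translated_parameters")) metabolite <- metabolite$drug
  k <- n_perturbable(drug) + if (!is.null(metabolite)) n_perturbable(metabolite) else 0L
  draws <- individual_draws(spec, index, k)
  d <- perturb_record(drug, draws)
  m <- NULL
  if (!is.null(metabolite)) {
    m <- perturb_record(metabolite, draws[-seq_len(attr(d, "n_draws"))])
  }
  list(drug = d, metabolite = m, multipliers = draws)
}

#' Simulate a virtual population
#'
#' Simulates `spec$n` virtual individuals, returning the pointwise 5th/95th
#' percentile band and arithmetic mean of the plasma concentration curves,
#' together with per-individual non-compartmental summaries.  An individual
#' whose integration fails is logged and redrawn from a fresh substream.
#'
#' @param drug,metabolite base records (or [translate_drug()] outputs).
#' @param phys a [physiology_set()].
#' @param regimen a [dose_regimen()].
#' @param spec a [population_spec()].
#' @param t_end simulation horizon (min).
#' @param times output grid (min); the default uses 2-min resolution which
#'   is ample for percentile bands.
#' @param t_last AUC truncation for the per-individual summaries.
#' @return an object of class `population_result`: list with `time`, `bands`
#'   (per-analyte list of data.frames with columns `p5`, `mean`, `p95`),
#'   `summaries` (data.frame, one row per individual and analyte),
#'   `n_resampled`, and the base-case `base` simulation.
#' @export
simulate_population <- function(drug, phys, regimen, spec,
                                metabolite = NULL,
                                t_end = 2880, times = NULL, t_last = NULL) {
  if (is.null(times)) times <- seq(0, t_end, by = 2)
  base_sys <- build_system(drug, phys, regimen, metabolite = metabolite)
  base <- simulate_profile(base_sys, t_end = t_end, times = times)
  analytes <- names(base$conc)
  curves <- lapply(analytes, function(a)
    matrix(NA_real_, nrow = length(base$time), ncol = spec$n))
  names(curves) <- analytes
  summaries <- vector("list", spec$n)
  n_resampled <- 0L
  draw_index <- 0L
  for (i in seq_len(spec$n)) {
    repeat {
      draw_index <- draw_index + 1L
      ind <- sample_individual(drug, spec, draw_index, metabolite = metabolite)
      res <- tryCatch({
        sys_i <- build_system(ind$drug, phys, regimen, metabolite = ind$metabolite)
        simulate_profile(sys_i, t_end = t_end, times = times)
      }, error = function(e) e)
      if (!inherits(res, "error")) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > spec$n) stop("too many failed individuals", call. = FALSE)
    }
    for (a in analytes) curves[[a]][, i] <- res$conc[[a]]
    summaries[[i]] <- do.call(rbind, lapply(analytes, function(a) {
      s <- pk_summary(res, analyte = a, t_last = t_last)
      s$individual <- i
      s
    }))
  }
  bands <- lapply(curves, function(m) {
    data.frame(p5 = apply(m, 1, stats::quantile, probs = 0.05, names = FALSE),
               mean = rowMeans(m),
               p95 = apply(m, 1, stats::quantile, probs = 0.95, names = FALSE))
  })
  structure(
    list(time = base$time, bands = bands,
         summaries = do.call(rbind, summaries),
         n = spec$n, n_resampled = n_resampled, base = base),
    class = "population_result"
  )
}

#' @export
print.population_result <- function(x, ...) {
  cat(sprintf("<population_result: %d individuals%s>\n", x$n,
              if (x$n_resampled) sprintf(" (%d resampled)", x$n_resampled) else ""))
  for (a in names(x$bands)) {
    s <- x$summaries[x$summaries$analyte == a, ]
    cat(sprintf("  %s: mean AUC0-t %.4g ug.h/mL (5th-95th of individuals %.4g-%.4g)\n",
                a, mean(s$auc0_t),
                stats::quantile(s$auc0_t, 0.05, names = FALSE),
                stats::quantile(s$auc0_t, 0.95, names = FALSE)))
  }
  invisible(x)
}
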