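# Consensus GA-PLS descriptor selection. A binary chromosome encodes
# descriptor inclusion; fitness is the cross-validated RMSE of a PLS model
# on the calibration set (latent-variable count picked by the same CV, up
# to a cap). The GA is run several times from different seeds and the final
# subset is the consensus of the per-run winners, which damps the tendency
# of any single run to overfit individual samples.

#' GA-PLS configuration
#'
#' Defaults follow the reference settings: population 64, at most 100
#' generations, per-gene mutation rate 0.005, window width 1 (each gene is
#' a single descriptor), convergence when 50% of the population shares the
#' best fitness, 30% of genes on in the initial population, double (two
#' point) crossover, 10 runs.
#'
#' @param population_size,max_generations,mutation_rate,window_width
#'   Core GA parameters.
#' @param convergence Fraction of the population sharing the best fitness
#'   that terminates a run early.
#' @param initial_terms_fraction Probability a gene starts switched on.
#' @param crossover Number of crossover points (2 = double).
#' @param n_runs Independent seeded GA runs feeding the consensus.
#' @param max_latent_variables Cap on PLS components inside the fitness.
#' @param cv_folds Folds for the fitness cross-validation.
#' @param consensus_threshold Minimum fraction of runs that must select a
#'   descriptor for it to enter the consensus subset.
#' @param seed Base RNG seed; run r uses `seed + r`.
#' @return A `ga_pls_config` list.
#' @export
ga_pls_config <- function(population_size = 64, max_generations = 100,
                          mutation_rate = 0.005, window_width = 1,
                          convergence = 0.5, initial_terms_fraction = 0.30,
                          crossover = 2, n_runs = 10,
                          max_latent_variables = 10, cv_folds = 5,
                          consensus_threshold = 0.5, seed = 1) {
  stopifnot(population_size >= 4, max_generations >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            window_width == 1, convergence > 0, convergence <= 1,
            initial_terms_fraction > 0, initial_terms_fraction <= 1,
            crossover %in% 1:2, n_runs >= 1, cv_folds >= 2)
  structure(as.list(environment()), class = "ga_pls_config")
}

.chrom_key <- function(chrom) paste(which(chrom), collapse = ",")

# One GA run; X is the (scaled) calibration matrix, fitness cache shared.
.ga_run <- function(X, y, cfg, run_seed, cache) {
  p <- ncol(X); n <- nrow(X)
  set.seed(run_seed)
  fold <- sample(rep(seq_len(cfg$cv_folds), length.out = n))

  fitness_of <- function(chrom) {
    key <- .chrom_key(chrom)
    f <- cache[[key]]
    if (!is.null(f)) return(f)
    cols <- which(chrom)
    rm <- pls_cv_rmse(X[, cols, drop = FALSE], y, fold,
                      min(cfg$max_latent_variables, length(cols)))
    f <- min(rm)
    cache[[key]] <- f
    f
  }

  pop <- matrix(stats::runif(cfg$population_size * p) <
                  cfg$initial_terms_fraction,
                nrow = cfg$population_size)
  empty <- rowSums(pop) == 0
  if (any(empty)) {
    pop[cbind(which(empty), sample.int(p, sum(empty), replace = TRUE))] <- TRUE
  }

  best_fit <- Inf; best_chrom <- NULL; gens <- 0L
  for (g in seq_len(cfg$max_generations)) {
    gens <- g
    fit <- apply(pop, 1, fitness_of)
    if (min(fit) < best_fit) {
      best_fit <- min(fit)
      best_chrom <- pop[which.min(fit), ]
    }
    if (mean(fit <= best_fit + 1e-12) >= cfg$convergence) break
    # tournament selection (size 2), elitism of 1
    pick <- function() {
      ij <- sample.int(cfg$population_size, 2)
      ij[which.min(fit[ij])]
    }
    children <- matrix(FALSE, cfg$population_size, p)
    children[1, ] <- pop[which.min(fit), ]
    i <- 2L
    while (i <= cfg$population_size) {
      pa <- pop[pick(), ]; pb <- pop[pick(), ]
      if (cfg$crossover == 2 && p > 2) {
        cut <- sort(sample.int(p - 1, 2))
        mid <- (cut[1] + 1):cut[2]
        ca <- pa; ca[mid] <- pb[mid]
        cb <- pb; cb[mid] <- pa[mid]
      } else {
        cut <- sample.int(p - 1, 1)
        ca <- c(pa[1:cut], pb[(cut + 1):p])
        cb <- c(pb[1:cut], pa[(cut + 1):p])
      }
      children[i, ] <- ca
      if (i + 1L <= cfg$population_size) children[i + 1L, ] <- cb
      i <- i + 2L
    }
    flip <- matrix(stats::runif(length(children)) < cfg$mutation_rate,
                   nrow = nrow(children))
    children <- xor(children, flip)
    empty <- rowSums(children) == 0
    if (any(empty)) {
      children[cbind(which(empty),
                     sample.int(p, sum(empty), replace = TRUE))] <- TRUE
    }
    pop <- children
  }
  list(chromosome = best_chrom, fitness = best_fit, generations = gens)
}

#' Consensus GA-PLS descriptor selection
#'
#' Runs the GA `n_runs` times with distinct seeds on the calibration data
#' and keeps every descriptor selected by at least
#' `consensus_threshold` of the run winners (ranked by their best CV RMSE;
#' if the consensus is empty the single best run's subset is returned).
#' Deterministic for a fixed seed.
#'
#' @param X Calibration descriptor matrix (autoscaled).
#' @param y Calibration response.
#' @param config A [ga_pls_config()].
#' @return List with `selected` (descriptor names), `frequency` (per
#'   descriptor, fraction of runs selecting it), and `runs` (per-run best
#'   fitness, subset size, generations, chromosome).
#' @export
ga_pls_select <- function(X, y, config = ga_pls_config()) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (is.null(colnames(X))) colnames(X) <- paste0("d", seq_len(ncol(X)))
  if (ncol(X) == 1L) {
    return(list(selected = colnames(X),
                frequency = stats::setNames(1, colnames(X)),
                runs = data.frame(run = 1, fitness = NA, n_selected = 1,
                                  generations = 0)))
  }
  cache <- new.env(parent = emptyenv())
  runs <- lapply(seq_len(config$n_runs), function(r) {
    .ga_run(X, y, config, config$seed + r, cache)
  })
  fits <- vapply(runs, `[[`, 0, "fitness")
  chroms <- do.call(rbind, lapply(runs, `[[`, "chromosome"))
  freq <- colMeans(chroms)
  names(freq) <- colnames(X)
  selected <- colnames(X)[freq >= config$consensus_threshold]
  if (!length(selected)) {
    selected <- colnames(X)[chroms[which.min(fits), ]]
  }
  list(selected = selected, frequency = freq,
       runs = data.frame(run = seq_len(config$n_runs), fitness = fits,
                         n_selected = rowSums(chroms),
                         generations = vapply(runs, `[[`, 0L, "generations")),
       chromosomes = chroms)
}
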