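#' Spike-and-slab dwell-time mixture
#'
#' Bout-duration distributions of vigilance states are heavily right-skewed
#' and decompose into "spikes" (short but frequent bouts) and "slabs"
#' (long-lasting but rare bouts). The simulator draws dwell lengths, in
#' epochs, from a two-component mixture of shifted geometric distributions:
#' with probability `p_short` a short bout of mean `mean_short_epochs`,
#' otherwise a long bout of mean `mean_long_epochs`. Each component is
#' `1 + Geometric`, so every bout lasts at least one epoch and the mixture
#' mean is `p_short * mean_short + (1 - p_short) * mean_long`.
#'
#' @param p_short Probability of the short (spike) component, in `[0, 1]`.
#' @param mean_short_epochs,mean_long_epochs Component means in epochs
#'   (both >= 1; short <= long).
#' @return An object of class `dwell_mixture`.
#' @export
dwell_mixture <- function(p_short, mean_short_epochs, mean_long_epochs) {
  stopifnot(p_short >= 0, p_short <= 1,
            mean_short_epochs >= 1, mean_long_epochs >= 1,
            mean_short_epochs <= mean_long_epochs)
  structure(list(p_short = p_short,
                 mean_short_epochs = mean_short_epochs,
                 mean_long_epochs = mean_long_epochs),
            class = "dwell_mixture")
}

draw_dwell <- function(mix, n = 1L) {
  # 1 + Geometric(p) has mean 1/p, so p = 1/mean
  short <- stats::runif(n) < mix$p_short
  p <- ifelse(short, 1 / mix$mean_short_epochs, 1 / mix$mean_long_epochs)
  1L + stats::rgeom(n, p)
}

#' Expected dwell length of a mixture, in epochs
#' @param mix A [dwell_mixture].
#' @return Mean bout length in epochs.
#' @export
dwell_mean <- function(mix) {
  mix$p_short * mix$mean_short_epochs +
    (1 - mix$p_short) * mix$mean_long_epochs
}

#' Simulation configuration for a semi-Markov hypnogram study
#'
#' @param P Named list (one element per treatment) of lists (one per hour)
#'   of K-by-K embedded transition matrices over `states`: zero diagonal,
#'   rows summing to 1. Row i gives the next-state probabilities on leaving
#'   state i.
#' @param dwell Named list of [dwell_mixture] objects, one per state,
#'   shared across treatments and hours: the generative counterpart of a
#'   drug that changes transition frequencies but not state durations.
#' @param states State labels (default the six raw states; REMS is
#'   simulated unsplit — splitting happens downstream).
#' @param n_subjects,n_epochs Study dimensions (defaults 6 subjects, 2700
#'   epochs = 3 h).
#' @param epoch_seconds Epoch length (default 4 s).
#' @param initial_state State at epoch 0 (default `"AW"`: animals are awake
#'   at drug administration).
#' @param seed Master seed; the whole study is a pure function of the
#'   config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(P, dwell, states = RAW_STATES, n_subjects = 6L,
                       n_epochs = 2700L, epoch_seconds = 4,
                       initial_state = "AW", seed = 20190831L) {
  cfg <- structure(list(states = states, P = P, dwell = dwell,
                        n_subjects = as.integer(n_subjects),
                        n_epochs = as.integer(n_epochs),
                        epoch_seconds = epoch_seconds,
                        initial_state = initial_state,
                        seed = as.integer(seed)),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  K <- length(cfg$states)
  if (!setequal(names(cfg$dwell), cfg$states)) {
    stop("dwell mixtures must be named by state")
  }
  for (trt in names(cfg$P)) {
    for (hr in seq_along(cfg$P[[trt]])) {
      M <- cfg$P[[trt]][[hr]]
      if (!is.matrix(M) || any(dim(M) != K)) {
        stop(sprintf("P[[%s]][[%d]] is not %dx%d", trt, hr, K, K))
      }
      if (any(abs(diag(M)) > 0)) {
        stop(sprintf("P[[%s]][[%d]] has nonzero diagonal", trt, hr))
      }
      if (any(abs(rowSums(M) - 1) > 1e-9)) {
        stop(sprintf("P[[%s]][[%d]] rows must sum to 1", trt, hr))
      }
      if (any(M < 0)) stop("transition probabilities must be non-negative")
    }
  }
  if (!(cfg$initial_state %in% cfg$states)) stop("invalid initial_state")
  if (cfg$n_subjects < 1L || cfg$n_epochs < 1L) stop("invalid dimensions")
  invisible(cfg)
}

# Column-tilt helper: multiply selected columns of a zero-diagonal row-
# stochastic matrix and renormalize each row.
tilt_matrix <- function(M, tilt) {
  for (s in names(tilt)) M[, s] <- M[, s] * tilt[[s]]
  diag(M) <- 0
  M / rowSums(M)
}

#' Default simulation configuration: 3 treatments x 3 hours
#'
#' A fully specified study mimicking the qualitative structure of a
#' crossover experiment with a wake-promoting dose-dependent drug
#' (vehicle `VEH`, low dose `AM5`, high dose `AM10`; 6 subjects; 3 h of
#' 4-s epochs). The vehicle matrices route traffic along
#' AW <-> PW <-> S1 -> S2 with S2 -> IS/REMS -> IS returns, and relax the
#' wake-wake traffic over the three hours; the dosed matrices tilt every
#' row toward AW and starve IS (low dose) and additionally S2 (high dose),
#' most strongly in the first hour. Dwell mixtures are shared across
#' treatments: the drug acts purely through transition frequencies, not
#' state durations. All probability values are qualitative mimics of
#' rodent sleep architecture, not estimates from any animal.
#'
#' @param seed Master seed stored in the config.
#' @return A `sim_config`.
#' @export
default_sim_config <- function(seed = 20190831L) {
  states <- RAW_STATES
  base <- function(rows) {
    M <- do.call(rbind, rows)
    dimnames(M) <- list(from = states, to = states)
    M
  }
  #              AW    PW    S1    S2    IS  REMS
  veh1 <- base(list(
    AW   = c(0.00, 0.70, 0.25, 0.02, 0.01, 0.02),
    PW   = c(0.55, 0.00, 0.35, 0.04, 0.02, 0.04),
    S1   = c(0.15, 0.35, 0.00, 0.40, 0.05, 0.05),
    S2   = c(0.08, 0.10, 0.42, 0.00, 0.25, 0.15),
    IS   = c(0.05, 0.05, 0.15, 0.35, 0.00, 0.40),
    REMS = c(0.22, 0.18, 0.10, 0.10, 0.40, 0.00)))
  # hours 2-3: wake-wake traffic relaxes, sleep-directed traffic grows
  veh2 <- tilt_matrix(veh1, list(PW = 0.7, AW = 0.7, S2 = 1.4, REMS = 1.5))
  veh3 <- tilt_matrix(veh1, list(PW = 0.55, AW = 0.55, S2 = 1.6, REMS = 2.0))
  # low dose: rows tilt toward AW, IS starved (strongest in hour 1)
  am5 <- list(tilt_matrix(veh1, list(AW = 1.9, IS = 0.10, REMS = 0.4)),
              tilt_matrix(veh2, list(AW = 1.6, IS = 0.35, REMS = 0.6)),
              tilt_matrix(veh3, list(AW = 1.4, IS = 0.55, REMS = 0.8)))
  # high dose: stronger AW tilt, S2 starved as well
  am10 <- list(tilt_matrix(veh1, list(AW = 2.8, IS = 0.10, S2 = 0.25,
                                      REMS = 0.25)),
               tilt_matrix(veh2, list(AW = 2.3, IS = 0.25, S2 = 0.40,
                                      REMS = 0.45)),
               tilt_matrix(veh3, list(AW = 1.9, IS = 0.40, S2 = 0.55,
                                      REMS = 0.65)))
  P <- list(VEH = list(veh1, veh2, veh3), AM5 = am5, AM10 = am10)
  dwell <- list(
    AW   = dwell_mixture(0.60, 2, 30),
    PW   = dwell_mixture(0.60, 2, 15),
    S1   = dwell_mixture(0.60, 2, 12),
    S2   = dwell_mixture(0.40, 3, 40),
    IS   = dwell_mixture(0.70, 2, 8),
    REMS = dwell_mixture(0.60, 2, 25)
  )
  sim_config(P = P, dwell = dwell, states = states, seed = seed)
}

# Documented deterministic per-hypnogram seed: a small integer hash of
# (master seed, subject index, treatment index), kept below 2^31.
derive_seed <- function(master, subject_idx, treatment_idx) {
  as.integer((as.numeric(master) * 7919 + subject_idx * 1009 +
                treatment_idx * 104729) %% 2147483647)
}

#' Simulate one hypnogram from a semi-Markov chain
#'
#' Alternates draws of dwell length (from the current state's
#' [dwell_mixture]) and next state (from the row of the embedded transition
#' matrix in force at the transition epoch) until `n_epochs` epochs are
#' generated; the final bout is truncated at the recording end. Hour
#' regimes switch at epoch 900 and 1800 boundaries (hours beyond the last
#' configured matrix reuse it). A fixed `(seed, subject, treatment)` gives
#' a bit-identical sequence.
#'
#' @param cfg A `sim_config`.
#' @param subject Subject label.
#' @param treatment Treatment label; must name an element of `cfg$P`.
#' @param seed Integer seed for this hypnogram (see [simulate_study()] for
#'   the derived default).
#' @return A [hypnogram].
#' @export
simulate_hypnogram <- function(cfg, subject, treatment, seed) {
  validate_sim_config(cfg)
  if (!(treatment %in% names(cfg$P))) {
    stop(sprintf("treatment %s not in config", treatment))
  }
  Phrs <- cfg$P[[treatment]]
  n_hours <- length(Phrs)
  epochs_per_hour <- as.integer(round(3600 / cfg$epoch_seconds))
  states <- character(cfg$n_epochs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% 2147483647))
  pos <- 0L
  state <- cfg$initial_state
  while (pos < cfg$n_epochs) {
    d <- draw_dwell(cfg$dwell[[state]])
    end <- min(pos + d, cfg$n_epochs)
    states[(pos + 1L):end] <- state
    pos <- pos + d
    if (pos >= cfg$n_epochs) break
    hour <- min(pos %/% epochs_per_hour + 1L, n_hours)
    state <- sample(cfg$states, 1L, prob = Phrs[[hour]][state, ])
  }
  hypnogram(subject, treatment, states, epoch_seconds = cfg$epoch_seconds)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a full crossover study
#'
#' Generates `n_subjects` hypnograms per treatment with per-hypnogram seeds
#' derived deterministically from `cfg$seed` and the subject and treatment
#' indices, so the entire study is a pure function of the config.
#'
#' @param cfg A `sim_config`.
#' @return Named list of [hypnogram] objects (`subject.treatment`).
#' @export
simulate_study <- function(cfg) {
  validate_sim_config(cfg)
  treatments <- names(cfg$P)
  out <- list()
  for (ti in seq_along(treatments)) {
    for (si in seq_len(cfg$n_subjects)) {
      subject <- sprintf("rat%02d", si)
      seed <- derive_seed(cfg$seed, si, ti)
      h <- simulate_hypnogram(cfg, subject, treatments[ti], seed)
      out[[sprintf("%s.%s", subject, treatments[ti])]] <- h
    }
  }
  out
}

#' Write a simulation configuration to YAML
#'
#' @param cfg A `sim_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  obj <- list(
    states = as.list(cfg$states),
    n_subjects = cfg$n_subjects,
    n_epochs = cfg$n_epochs,
    epoch_seconds = cfg$epoch_seconds,
    initial_state = cfg$initial_state,
    seed = cfg$seed,
    dwell = lapply(cfg$dwell, function(m) {
      list(p_short = m$p_short,
           mean_short_epochs = m$mean_short_epochs,
           mean_long_epochs = m$mean_long_epochs)
    }),
    P = lapply(cfg$P, function(hrs) {
      lapply(hrs, function(M) lapply(seq_len(nrow(M)),
                                     function(i) as.list(unname(M[i, ]))))
    })
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path Path written by [write_sim_config()].
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  states <- unlist(obj$states)
  K <- length(states)
  dwell <- lapply(obj$dwell, function(m) {
    dwell_mixture(m$p_short, m$mean_short_epochs, m$mean_long_epochs)
  })
  P <- lapply(obj$P, function(hrs) {
    lapply(hrs, function(rows) {
      M <- do.call(rbind, lapply(rows, unlist))
      dimnames(M) <- list(from = states, to = states)
      M
    })
  })
  sim_config(P = P, dwell = dwell, states = states,
             n_subjects = obj$n_subjects, n_epochs = obj$n_epochs,
             epoch_seconds = obj$epoch_seconds,
             initial_state = obj$initial_state, seed = obj$seed)
}
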