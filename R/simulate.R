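#' Simulate differential-conditioning data
#'
#' Draws per-participant (CS1, CS2) response pairs from a bivariate
#' normal distribution with condition means `mu1`/`mu2`, common
#' within-condition standard deviation `sigma`, and within-subject
#' correlation `rho` — the noise model the paired t-test assumes. With
#' `groups = 2` a second group of the same size is drawn with its own
#' mean pair (`mu1_2`/`mu2_2`, defaulting to the first group's). The
#' implied standardized paired effect is
#' delta = (mu1 - mu2) / (sigma * sqrt(2 * (1 - rho))); see
#' [implied_delta()].
#'
#' Reproducibility is exact under a seed: the Mersenne-Twister /
#' inversion generator is set explicitly (not the session default), and
#' the caller's RNG state is restored afterwards.
#'
#' @param n Participants per group (>= 2).
#' @param mu1,mu2 Condition means, in CR units (e.g. microvolts of
#'   startle EMG).
#' @param sigma Within-condition standard deviation (> 0).
#' @param rho Within-subject CS1-CS2 correlation, in (-1, 1).
#' @param groups 1 (default) or 2.
#' @param mu1_2,mu2_2 Second group's condition means (used when
#'   `groups = 2`); default to `mu1`/`mu2`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A [cs_table][as_cs_table] tibble with `n * groups` rows, with
#'   the implied `delta` attached as attribute `"delta"`.
#' @examples
#' simulate_cs(n = 10, mu1 = 5, mu2 = 3, sigma = 2, rho = 0.5, seed = 42)
#' @export
simulate_cs <- function(n, mu1 = 0, mu2 = 0, sigma = 1, rho = 0.5,
                        groups = 1, mu1_2 = mu1, mu2_2 = mu2,
                        seed = NULL) {
  check_n(n, "n")
  stopifnot(
    is.numeric(sigma), length(sigma) == 1L, sigma > 0,
    is.numeric(rho), length(rho) == 1L, abs(rho) < 1
  )
  if (!groups %in% c(1, 2)) abort("`groups` must be 1 or 2.")
  draw <- function() {
    mus <- list(c(mu1, mu2), c(mu1_2, mu2_2))[seq_len(groups)]
    blocks <- lapply(seq_len(groups), function(g) {
      z1 <- rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
      tibble(
        cs1 = mus[[g]][1L] + sigma * z1,
        cs2 = mus[[g]][2L] + sigma * z2,
        group = g
      )
    })
    dplyr::bind_rows(blocks)
  }
  out <- if (is.null(seed)) {
    draw()
  } else {
    withr::with_seed(as.integer(seed), draw(),
      .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion"
    )
  }
  out$subject_id <- as.character(seq_len(nrow(out)))
  if (groups == 1L) out$group <- NULL else out$group <- paste0("g", out$group)
  out <- validate_cs_table(
    out[, intersect(c("subject_id", "cs1", "cs2", "group"), names(out))]
  )
  attr(out, "delta") <- implied_delta(mu1, mu2, sigma, rho)
  out
}

#' Standardized paired effect implied by simulation parameters
#'
#' The paired design tests the difference scores d = CS1 - CS2, whose
#' standard deviation under the bivariate-normal generator is
#' sigma * sqrt(2 * (1 - rho)); the standardized paired effect is the
#' mean difference divided by that.
#'
#' @inheritParams simulate_cs
#' @return The standardized effect size delta.
#' @export
implied_delta <- function(mu1, mu2, sigma, rho) {
  (mu1 - mu2) / (sigma * sqrt(2 * (1 - rho)))
}

#' Batch of null-configuration conditioning tables
#'
#' Generates `reps` independent tables from a no-effect configuration
#' (`mu1 == mu2`), for calibration studies such as empirical type-I
#' error rates or evidence-for-the-null checks. Replicate seeds are
#' derived from the base seed by a counter scheme
#' (`seed + rep` index, wrapped into the 32-bit integer range), so any
#' single replicate can be regenerated on its own with
#' [simulate_cs()].
#'
#' @inheritParams simulate_cs
#' @param reps Number of replicate tables (>= 1).
#' @param seed Base integer seed.
#' @return A list of `reps` [cs_table][as_cs_table] tibbles.
#' @examples
#' batch <- null_batch(n = 10, sigma = 1, rho = 0.5, reps = 3, seed = 7)
#' length(batch)
#' @export
null_batch <- function(n, mu = 0, sigma = 1, rho = 0.5, reps, seed) {
  stopifnot(is.numeric(reps), length(reps) == 1L, reps >= 1)
  lapply(derive_seeds(seed, reps), function(s) {
    simulate_cs(
      n = n, mu1 = mu, mu2 = mu, sigma = sigma, rho = rho,
      seed = s
    )
  })
}

derive_seeds <- function(seed, reps) {
  (as.double(seed) + seq_len(reps)) %% .Machine$integer.max
}
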