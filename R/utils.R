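#' Evaluate an expression under a local, explicit random seed
#'
#' Every stochastic operation in the package routes its randomness through
#' this helper so that a call is a pure function of its `seed` argument:
#' the global RNG state is saved, the seed is set, and the previous state is
#' restored on exit.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
inv_logit <- function(x) stats::plogis(x)

# Factor level vocabulary shared by the design machinery, the simulators and
# the scenario builders. Reference levels come first.
.treatment_levels <- c("before", "early", "ongoing", "after", "unassigned")
.tod_levels <- c("day", "night", "twilight")
.season_levels <- c("summer", "winter", "excluded")
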