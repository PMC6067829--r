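#' Build the 13 x 13 mixed-gambles grid
#'
#' Constructs every distinct gain--loss pair offered by the task: potential
#' gains run from +6 to +30 euro in steps of 2 euro and potential losses from
#' 3 to 15 euro in steps of 1 euro (stored as positive magnitudes). Each
#' gamble is a 50/50 lottery, so the grid carries fixed outcome probabilities
#' of 0.5. The asymmetric gain--loss range assumes people are roughly twice
#' as sensitive to losses as to gains, which centres behaviour away from
#' floor and ceiling.
#'
#' @return A tibble with 169 rows and columns `gain`, `loss` (positive
#'   magnitude, euros), `p_gain` and `p_loss` (both 0.5).
#' @examples
#' grid <- build_gamble_grid()
#' nrow(grid) # 169
#' @export
build_gamble_grid <- function() {
  grid <- tidyr::expand_grid(
    gain = seq(6, 30, by = 2),
    loss = seq(3, 15, by = 1)
  )
  grid$p_gain <- 0.5
  grid$p_loss <- 0.5
  tibble::as_tibble(grid)
}

#' Build a randomized trial schedule
#'
#' Permutes the 169-gamble grid into a seeded random presentation order and
#' splits it into three runs of sizes 57/56/56 (the closest-to-equal split of
#' 169). Each gain--loss pair appears exactly once per schedule.
#'
#' @param seed Integer seed; the same seed always yields the same schedule.
#' @return A tibble with columns `trial_index`, `run`, `gain`, `loss`,
#'   `p_gain`, `p_loss`. The seed is stored in the `"seed"` attribute.
#' @export
build_schedule <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  grid <- build_gamble_grid()
  ord <- with_local_seed(seed, sample.int(nrow(grid)))
  sched <- grid[ord, ]
  sched$trial_index <- seq_len(nrow(sched))
  sched$run <- rep(1:3, times = c(57, 56, 56))
  sched <- sched[, c("trial_index", "run", "gain", "loss", "p_gain", "p_loss")]
  attr(sched, "seed") <- as.integer(seed)
  sched
}

#' Write a schedule to CSV
#'
#' @param schedule A schedule from [build_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(
    schedule[, c("trial_index", "run", "gain", "loss")],
    path, row.names = FALSE
  )
  invisible(path)
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
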