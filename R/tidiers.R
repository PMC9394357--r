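# broom-style accessors for runs.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-record observables of a run
#'
#' @param x A `dpd_run`.
#' @param ... Unused.
#' @return The energy tibble in long form: `step`, `time`, `observable`
#'   (kinetic / pair / bond / angle / total / temperature) and `value`.
#' @export
tidy.dpd_run <- function(x, ...) {
  tidyr::pivot_longer(x$energy, cols = -c("step", "time"),
                      names_to = "observable", values_to = "value")
}

#' One-row summary of a run
#'
#' @param x A `dpd_run`.
#' @param ... Unused.
#' @return Tibble with bead/chain counts, steps, final time, final
#'   per-bead energy and temperature, stored frame count and overlap
#'   events.
#' @export
glance.dpd_run <- function(x, ...) {
  last <- x$energy[nrow(x$energy), ]
  comp <- x$composition
  tibble(n_beads = nrow(x$final_state$positions),
         n_chains = comp$n1 + comp$n2,
         nt1 = comp$topology1$n_tail, nt2 = comp$topology2$n_tail,
         n_steps = x$n_steps, dt = x$dt,
         t_final = x$final_state$time,
         energy = last$total, temperature = last$temperature,
         n_frames = length(x$frames), n_overlap = x$n_overlap,
         seed = x$seed)
}
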