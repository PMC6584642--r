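# Event and multiplier naming conventions shared across modules.
#
# Simple events: "1p","1m","2p","2m" = increase/decrease of shape component
# 1 or 2 in one substep. Correlated (adjacent-substep) event pairs are
# symmetric under order reversal: the pair (x alpha at t, y beta at t+dt) is
# identified with (y beta at t, x alpha at t+dt). Canonical key: the
# component-1 event (or, within one component, the "+" event) is written
# first. 16 ordered labels reduce to 10 canonical keys.

MC_SIMPLE_KEYS <- c("1p", "1m", "2p", "2m")
MC_CORR_KEYS <- c("11pp", "11pm", "11mm",
                  "22pp", "22pm", "22mm",
                  "12pp", "12pm", "12mp", "12mm")
MC_MULTIPLIER_NAMES <- paste0("l", c(MC_SIMPLE_KEYS, MC_CORR_KEYS))

# component and sign of each simple-event index 1..4
MC_EV_COMP <- c(1L, 1L, 2L, 2L)
MC_EV_SIGN <- c("p", "m", "p", "m")

# canonical correlated key for the ordered pair (event a at t, event b at t+dt)
mc_pair_key <- function(a, b) {
  ca <- MC_EV_COMP[a]; cb <- MC_EV_COMP[b]
  sa <- MC_EV_SIGN[a]; sb <- MC_EV_SIGN[b]
  if (ca == cb) {
    # within one component "pm" and "mp" are the same phenomenon
    signs <- sort(c(sa, sb))                    # "m","p" -> "pm" canonical
    key <- paste0(ca, cb, if (identical(signs, c("m", "p"))) "pm"
                          else paste0(sa, sb))
  } else if (ca == 1L) {
    key <- paste0("12", sa, sb)
  } else {
    key <- paste0("12", sb, sa)
  }
  key
}

# 4x4 lookup: MC_PAIR_KEY[a, b] canonical key of ordered pair (a then b)
MC_PAIR_KEY <- {
  m <- matrix("", 4, 4)
  for (a in 1:4) for (b in 1:4) m[a, b] <- mc_pair_key(a, b)
  dimnames(m) <- list(MC_SIMPLE_KEYS, MC_SIMPLE_KEYS)
  m
}

#' Count the event and observable labels of the two-component model
#'
#' Returns the structural counts of the event taxonomy: the number of joint
#' macroscopic event cases per substep (each component may increase,
#' decrease or stay, 3 x 3), the number of ordered adjacent-substep pair
#' labels (4 x 4), the number of distinct time-correlated observables after
#' order-reversal symmetry, and the total multiplier count (simple +
#' correlated).
#'
#' @return Named list with `joint_cases`, `ordered_pairs`,
#'   `correlated_observables`, `simple_observables`, `n_multipliers`.
#' @export
#' @examples
#' event_taxonomy()
event_taxonomy <- function() {
  list(
    joint_cases = 3L * 3L,
    ordered_pairs = length(MC_SIMPLE_KEYS)^2,
    correlated_observables = length(unique(as.vector(MC_PAIR_KEY))),
    simple_observables = length(MC_SIMPLE_KEYS),
    n_multipliers = length(MC_MULTIPLIER_NAMES)
  )
}

# map an event matrix (n x 2, values -1/0/1) to simple-event indicator
# columns 1p,1m,2p,2m (n x 4 logical)
mc_event_indicators <- function(events) {
  cbind(`1p` = events[, 1] == 1L, `1m` = events[, 1] == -1L,
        `2p` = events[, 2] == 1L, `2m` = events[, 2] == -1L)
}
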