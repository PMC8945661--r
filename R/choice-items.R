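#' Default intertemporal choice set
#'
#' Seven smaller-sooner / larger-later items spanning the published ranges of
#' the instrument (immediate rewards 840--3990 RMB, delayed rewards 2311--8190
#' RMB, delays 4--939 days), with endpoints included.  Amounts and delays are
#' placed so that the items' indifference rates \eqn{k^* = (LL/SS - 1)/D} are
#' approximately log-uniform from about 0.44 down to 0.0011 per day, giving the
#' set discriminating power across the range of discount rates adults
#' typically show.  The exact items of the original instrument are not public;
#' this set is a documented stand-in with the same ranges.
#'
#' @return A data.frame with columns `item_id`, `ss_amount`, `ll_amount`,
#'   `delay_days`.
#' @seealso [sample_choice_items()] for random item sets used in
#'   parameter-recovery simulations.
#' @export
#' @examples
#' default_choice_items()
default_choice_items <- function() {
  path <- system.file("extdata", "choice_items_default.csv", package = "ddcohort")
  if (nzchar(path)) {
    items <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    # fallback when running from a source tree
    items <- data.frame(
      item_id = paste0("item", 1:7),
      ss_amount = c(840, 1300, 1800, 2300, 2800, 3300, 3990),
      ll_amount = c(2311, 3000, 4000, 5000, 6000, 7000, 8190),
      delay_days = c(4, 15, 40, 100, 250, 500, 939)
    )
  }
  validate_items(items)
  items
}

#' Randomly sampled intertemporal items
#'
#' Draws items log-uniformly inside the instrument's printed ranges, with the
#' delayed amount constrained to exceed the immediate one.  Used to build the
#' dense item sets needed for parameter-recovery simulations, where the 7-item
#' instrument only interval-identifies the discount rate.
#'
#' @param n number of items.
#' @param seed optional integer seed.
#' @param ss_range,ll_range,delay_range numeric length-2 ranges.
#' @return data.frame like [default_choice_items()].
#' @export
sample_choice_items <- function(n, seed = NULL,
                                ss_range = c(840, 3990),
                                ll_range = c(2311, 8190),
                                delay_range = c(4, 939)) {
  stopifnot(n >= 1)
  with_seed(seed, {
    ss <- exp(runif(n, log(ss_range[1]), log(ss_range[2])))
    ll_lo <- pmax(ll_range[1], ss * 1.02)
    ll <- exp(runif(n, log(ll_lo), log(ll_range[2])))
    d <- exp(runif(n, log(delay_range[1]), log(delay_range[2])))
    data.frame(
      item_id = sprintf("r%04d", seq_len(n)),
      ss_amount = round(ss), ll_amount = round(ll), delay_days = round(d)
    )
  })
}

validate_items <- function(items) {
  req <- c("item_id", "ss_amount", "ll_amount", "delay_days")
  miss <- setdiff(req, names(items))
  if (length(miss)) stop_input("items table missing columns: ", paste(miss, collapse = ", "))
  if (any(duplicated(items$item_id))) stop_input("duplicate item_id in items table")
  bad <- !(items$ss_amount > 0 & items$ll_amount > items$ss_amount & items$delay_days > 0)
  if (any(bad)) {
    stop_input("invalid items (need 0 < ss_amount < ll_amount, delay_days > 0) at rows: ",
               paste(which(bad), collapse = ", "))
  }
  invisible(items)
}
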