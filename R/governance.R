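#' Government state
#'
#' @param gov the \code{governance} configuration section.
#' @return a list carrying the policy parameters and the (initially
#'   inactive) intervention flag. Intervention activates at most once per
#'   run and persists.
#' @export
make_government <- function(gov) {
  list(
    critical_biomass_fraction = gov$critical_biomass_fraction,
    restoration_capacity = gov$restoration_capacity,
    tech_investment_cap = gov$tech_investment_cap,
    speculation_cap = gov$speculation_cap,
    protection_increment = gov$protection_increment,
    restoration_mandate = isTRUE(gov$restoration_mandate),
    intervention_active = FALSE
  )
}

#' Conservation-policy trigger
#'
#' Intervention triggers when the total resource stock falls strictly below
#' the critical-biomass-stock fraction of the initial stock. A fraction of
#' zero therefore never triggers (the no-intervention scenarios).
#'
#' @param total_stock current total resource stock.
#' @param initial_stock initial total stock (positive).
#' @param gov a government list.
#' @return \code{TRUE} if policies should activate.
#' @export
check_trigger <- function(total_stock, initial_stock, gov) {
  stopifnot(initial_stock > 0)
  total_stock < gov$critical_biomass_fraction * initial_stock
}

#' Apply conservation policies
#'
#' The one-off structural part of the policy package, executed at
#' activation: the protected-area network is enlarged by
#' \code{protection_increment} (as a fraction of all patches, drawn among
#' unprotected ones). The continuing parts — the technology-investment cap,
#' the speculation cap with the block on new speculative borrowing, and the
#' restoration mandate — are enforced by the scheduler on every subsequent
#' tick while \code{intervention_active} is set. Calling this with an
#' inactive government returns the landscape unchanged.
#'
#' @param patches the patch data frame.
#' @param gov a government list.
#' @return a list: updated \code{patches} and \code{gov}.
#' @export
apply_policies <- function(patches, gov) {
  if (!isTRUE(gov$intervention_active)) {
    return(list(patches = patches, gov = gov))
  }
  target <- min(1, mean(patches$protected) + gov$protection_increment)
  patches <- designate_protected(patches, target)
  list(patches = patches, gov = gov)
}

# Per-tick restoration mandate: patches depleted by harvesting while the
# policy is active are flagged for restoration — up to the programme's
# per-tick enrolment capacity — provided the last harvester can fund the
# work; the restoration cost is recycled to the household sector as
# restoration labour income.
restoration_mandate_step <- function(patches, firms, households, econ,
                                     capacity = Inf) {
  paid <- 0
  enrolled <- 0
  idx <- which(patches$stock <= 0 & patches$harvested &
                 !patches$restoring & !is.na(patches$last_harvester))
  for (p in idx) {
    if (enrolled >= capacity) break
    f <- match(patches$last_harvester[p], firms$firm_id)
    if (is.na(f) || firms$bankrupt[f]) next
    if (firms$capital[f] >= econ$restoration_cost) {
      firms$capital[f] <- firms$capital[f] - econ$restoration_cost
      paid <- paid + econ$restoration_cost
      patches$restoring[p] <- TRUE
      enrolled <- enrolled + 1
    }
  }
  if (paid > 0 && nrow(households)) {
    households$capital <- households$capital + paid / nrow(households)
  }
  list(patches = patches, firms = firms, households = households,
       paid = paid)
}
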