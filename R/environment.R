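#' Create the patch landscape
#'
#' Builds the rectangular grid of land parcels. Coordinates are 0-based and
#' the grid is non-toroidal. Every patch starts unprotected with the
#' configured initial resource stock.
#'
#' @param env the \code{environment} section of a configuration.
#' @return a data frame with one row per patch: \code{patch_id}, \code{row},
#'   \code{col}, \code{stock}, \code{protected}, \code{restoring},
#'   \code{harvested}, \code{last_harvester}.
#' @export
make_patches <- function(env) {
  n <- env$grid_rows * env$grid_cols
  data.frame(
    patch_id = seq_len(n),
    row = rep(seq_len(env$grid_rows) - 1L, each = env$grid_cols),
    col = rep(seq_len(env$grid_cols) - 1L, times = env$grid_rows),
    stock = rep(as.numeric(env$initial_stock_per_patch), n),
    protected = rep(FALSE, n),
    restoring = rep(FALSE, n),
    harvested = rep(FALSE, n),
    last_harvester = rep(NA_integer_, n)
  )
}

#' Logistic resource regrowth
#'
#' Applies one tick of logistic growth, \eqn{R_s \leftarrow R_s + r R_s (1 -
#' R_s/K)}, to every ordinary (non-restoring) patch. Extinction is
#' absorbing: a patch at zero stock only recovers through restoration.
#' Stocks never exceed the carrying capacity and protection/restoration
#' flags are untouched. The per-patch growth increments are attached as the
#' \code{"growth"} attribute for mass-balance accounting.
#'
#' @param patches a patch data frame (any subset of rows).
#' @param env the \code{environment} configuration section.
#' @return the updated patch data frame.
#' @export
grow_resource <- function(patches, env) {
  if (any(patches$stock < 0)) {
    stop("corrupted state: negative resource stock", call. = FALSE)
  }
  K <- env$carrying_capacity
  r <- env$regrowth_rate
  inc <- numeric(nrow(patches))
  idx <- !patches$restoring & patches$stock > 0
  inc[idx] <- r * patches$stock[idx] * (1 - patches$stock[idx] / K)
  new_stock <- pmin(patches$stock + inc, K)
  inc <- new_stock - patches$stock
  patches$stock <- new_stock
  attr(patches, "growth") <- inc
  patches
}

#' Restore depleted land
#'
#' Applies one tick of mandated restoration: every patch flagged
#' \code{restoring} gains \code{restoration_rate} biomass (capped at the
#' carrying capacity) and leaves restoration once its stock reaches the
#' re-activation fraction of capacity. Calling this on any patch that is not
#' under restoration is a scheduling bug and raises an error.
#'
#' @inheritParams grow_resource
#' @return the updated patch data frame with a \code{"restoration"}
#'   attribute holding the per-patch increments.
#' @export
restore_patch <- function(patches, env) {
  if (!all(patches$restoring)) {
    stop("restore_patch() called on a patch not under restoration",
         call. = FALSE)
  }
  K <- env$carrying_capacity
  new_stock <- pmin(patches$stock + env$restoration_rate, K)
  inc <- new_stock - patches$stock
  patches$stock <- new_stock
  done <- patches$stock >= env$reactivation_fraction * K
  patches$restoring[done] <- FALSE
  attr(patches, "restoration") <- inc
  patches
}

# One tick of landscape dynamics: regrow ordinary patches, restore flagged
# ones. Returns the patches plus aggregate growth/restoration totals.
environment_step <- function(patches, env) {
  patches <- grow_resource(patches, env)
  growth <- sum(attr(patches, "growth"))
  restoration <- 0
  idx <- which(patches$restoring)
  if (length(idx)) {
    restored <- restore_patch(patches[idx, , drop = FALSE], env)
    restoration <- sum(attr(restored, "restoration"))
    patches$stock[idx] <- restored$stock
    patches$restoring[idx] <- restored$restoring
  }
  attr(patches, "growth") <- NULL
  list(patches = patches, growth = growth, restoration = restoration)
}

#' Total resource stock of the landscape
#'
#' @param patches a patch data frame.
#' @return the sum of \code{stock} over all patches.
#' @export
total_resource_stock <- function(patches) {
  sum(patches$stock)
}

#' Expand the protected-area network
#'
#' Protects patches until the protected count equals
#' \code{round(target_fraction * patch count)}. Expansion is monotone:
#' already-protected patches stay protected, and new ones are drawn
#' uniformly at random among the unprotected (the siting rule is
#' intentionally neutral). Uses the session RNG, so runs are reproducible
#' under a fixed seed.
#'
#' @param patches a patch data frame.
#' @param target_fraction desired protected fraction in \eqn{[0, 1]}.
#' @return the updated patch data frame.
#' @export
designate_protected <- function(patches, target_fraction) {
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      is.na(target_fraction) || target_fraction < 0 ||
      target_fraction > 1) {
    stop("target_fraction must be a single number in [0, 1]",
         call. = FALSE)
  }
  n_target <- round(target_fraction * nrow(patches))
  need <- n_target - sum(patches$protected)
  if (need > 0) {
    pool <- which(!patches$protected)
    pick <- if (length(pool) <= need) pool else sample(pool, need)
    patches$protected[pick] <- TRUE
  }
  patches
}
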