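#' Core behavioural rules of the coupled economy-resource model
#'
#' The eight algebraic rules that drive agent behaviour, exposed as pure
#' vectorized functions so they can be audited and tested independently of
#' the scheduler:
#' \describe{
#'   \item{biocapacity}{\eqn{B = R_s F_y F_{eq}}: capacity of a patch to
#'     produce useful biomass, from its resource stock scaled by the
#'     ecological-footprint yield and equivalence factors.}
#'   \item{extraction_target}{\eqn{R_e = \max(0, D L c E - B_r)}: biomass a
#'     firm seeks to extract to serve demand \eqn{D} with workforce \eqn{L},
#'     conversion factor \eqn{c} and extraction-technology efficiency
#'     \eqn{E}, net of its standing reserve \eqn{B_r}.}
#'   \item{demand_goods}{\eqn{D = H_c / (P v) \cdot e^{-\lambda d}}: a
#'     household's goods demand given spendable capital \eqn{H_c}, price
#'     \eqn{P}, accelerator \eqn{v} and grid distance \eqn{d}; spending is
#'     capped at the spendable capital.}
#'   \item{investment_required}{\eqn{K = AGD_{t-1} L F_c M_c}: the
#'     extraction-cost outlay needed to serve last tick's aggregate demand,
#'     zero when firm capital is negative.}
#'   \item{price_rule}{\eqn{P = D \max(P_k, p_0) / \max(B_r, b_0)}: price
#'     from firm-level demand, the speculation index \eqn{P_k} and the
#'     biomass reserve, with small floors guarding the degenerate cases.}
#'   \item{productivity_rule}{\eqn{p = (F_c(t) - F_c(t-1)) / L}, zero by
#'     convention for a firm with no workers.}
#'   \item{nominal_wage}{\eqn{W_n = W_c F_c / L}: per-worker wage from the
#'     payroll share \eqn{W_c} of firm capital.}
#'   \item{speculation_index}{\eqn{P_k = \max(k_g, 0) \cdot Y}: speculative
#'     pressure from the GDP growth rate and real output; betting volume
#'     cannot be negative.}
#' }
#'
#' @param stock,reserve non-negative biomass quantities.
#' @param yield_factor,equivalence_factor positive footprint factors.
#' @param demand goods demanded.
#' @param labour workforce size.
#' @param conversion goods produced per biomass x labour unit.
#' @param efficiency extraction-technology efficiency multiplier.
#' @param capital,capital_prev monetary capital.
#' @param price goods price (must be positive for \code{demand_goods}).
#' @param accelerator the demand accelerator \eqn{v} (positive).
#' @param distance grid distance between household and firm.
#' @param decay exponential distance-decay coefficient.
#' @param agd_prev previous-tick aggregate demand.
#' @param correction the extraction-demand correction factor \eqn{M_c}.
#' @param speculation the speculation index \eqn{P_k}.
#' @param speculation_floor,reserve_floor positive guards for the price
#'   rule.
#' @param wage_coefficient payroll share of firm capital, in \eqn{(0,1)}.
#' @param gdp_growth relative GDP growth rate \eqn{k_g}.
#' @param output real output \eqn{Y} (goods per tick).
#' @return a numeric vector.
#' @name core-rules
NULL

#' @rdname core-rules
#' @export
biocapacity <- function(stock, yield_factor, equivalence_factor) {
  stopifnot(all(stock >= 0), all(yield_factor > 0),
            all(equivalence_factor > 0))
  stock * yield_factor * equivalence_factor
}

#' @rdname core-rules
#' @export
extraction_target <- function(demand, labour, conversion, efficiency,
                              reserve) {
  pmax(0, demand * labour * conversion * efficiency - reserve)
}

#' @rdname core-rules
#' @export
demand_goods <- function(capital, price, accelerator, distance = 0,
                         decay = 0) {
  if (any(price <= 0)) stop("price must be positive", call. = FALSE)
  if (any(accelerator <= 0)) {
    stop("accelerator must be positive", call. = FALSE)
  }
  spendable <- pmax(capital, 0)
  d <- spendable / (price * accelerator) * exp(-decay * distance)
  pmin(d, spendable / price) # spending never exceeds available capital
}

#' @rdname core-rules
#' @export
investment_required <- function(agd_prev, labour, capital, correction) {
  ifelse(capital < 0, 0, agd_prev * labour * capital * correction)
}

#' @rdname core-rules
#' @export
price_rule <- function(demand, speculation, reserve,
                       speculation_floor = 1, reserve_floor = 1e-6) {
  demand * pmax(speculation, speculation_floor) /
    pmax(reserve, reserve_floor)
}

#' @rdname core-rules
#' @export
productivity_rule <- function(capital, capital_prev, labour) {
  ifelse(labour > 0, (capital - capital_prev) / pmax(labour, 1), 0)
}

#' @rdname core-rules
#' @export
nominal_wage <- function(wage_coefficient, capital, labour) {
  ifelse(labour > 0, wage_coefficient * capital / pmax(labour, 1), 0)
}

#' @rdname core-rules
#' @export
speculation_index <- function(gdp_growth, output) {
  pmax(gdp_growth, 0) * output
}

#' @rdname core-rules
#' @export
update_speculation <- speculation_index

#' Equal-principal loan installment
#'
#' One tick's payment due on a loan under equal-principal amortization:
#' the balance divided by the remaining term, plus interest on the whole
#' outstanding balance.
#'
#' @param balance outstanding principal.
#' @param ticks_remaining remaining term in ticks (positive).
#' @param rate per-tick credit interest rate.
#' @return a list with \code{principal}, \code{interest} and \code{total}.
#' @export
#' @examples
#' loan_installment(100, 10, 0.05) # pay 15: 10 principal + 5 interest
loan_installment <- function(balance, ticks_remaining, rate) {
  principal <- ifelse(ticks_remaining > 0,
                      balance / pmax(ticks_remaining, 1), balance)
  interest <- balance * rate
  list(principal = principal, interest = interest,
       total = principal + interest)
}
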