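# Converting PAF series into dollars: sector expenditure attribution,
# CPI inflation to 2014 CAD, and the constant-baseline avoided-cost
# counterfactual.

#' Build a CPI series
#'
#' Constant-growth consumer price index with a base year at which the
#' ratio is 1.
#'
#' @param years Integer years to cover.
#' @param growth Annual growth rate.
#' @param base_year Base year (index 1).
#' @return Data frame (year, cpi).
#' @export
cpi_series <- function(years, growth = 0.018, base_year = 2014) {
  years <- sort(unique(as.integer(years)))
  data.frame(year = years, cpi = (1 + growth)^(years - base_year))
}

#' Inflate a nominal amount to 2014 dollars
#'
#' @param amount Nominal amount(s).
#' @param year Year(s) of the amount.
#' @param cpi CPI data frame (year, cpi) with base year 2014.
#' @return Amount(s) in 2014 dollars: `amount * cpi(2014) / cpi(year)`.
#' @export
inflate_to_2014 <- function(amount, year, cpi) {
  stopifnot(all(c("year", "cpi") %in% names(cpi)))
  base <- cpi$cpi[cpi$year == 2014]
  if (length(base) != 1L) stop("CPI series must contain the base year 2014")
  idx <- match(year, cpi$year)
  if (anyNA(idx))
    stop("CPI series is missing year(s): ",
         paste(unique(year[is.na(idx)]), collapse = ", "))
  amount * base / cpi$cpi[idx]
}

#' Deflate a 2014 amount back to nominal dollars
#'
#' Inverse of [inflate_to_2014()].
#'
#' @inheritParams inflate_to_2014
#' @return Nominal amount(s).
#' @export
deflate_from_2014 <- function(amount, year, cpi) {
  amount / inflate_to_2014(1, year, cpi)
}

#' Inflate an expenditure table to 2014 dollars
#'
#' Applies [inflate_to_2014()] to every row and tags the result with a
#' currency-year attribute; applying it twice is an error, so every
#' amount flows through inflation exactly once.
#'
#' @param expenditures Data frame (fiscal_year, sector, amount), nominal.
#' @param cpi CPI data frame.
#' @return The table with `amount` in 2014 dollars and attribute
#'   `currency_year = 2014`.
#' @export
inflate_expenditures <- function(expenditures, cpi) {
  if (identical(attr(expenditures, "currency_year"), 2014))
    stop("expenditure table is already in 2014 dollars; refusing to inflate twice")
  stopifnot(all(c("fiscal_year", "sector", "amount") %in% names(expenditures)))
  expenditures$amount <- inflate_to_2014(expenditures$amount,
                                         expenditures$fiscal_year, cpi)
  attr(expenditures, "currency_year") <- 2014
  expenditures
}

#' Attribute sector expenditures to risks via the PAF series
#'
#' attributable(risk, sector, year) = PAF(risk, sector, year) x
#' expenditure(sector, year).  The `other` sector carries no PAF of its
#' own: the community-care PAF is applied to its expenditure.  The
#' expenditure table must already be in 2014 dollars (see
#' [inflate_expenditures()]).
#'
#' @param pafs Data frame (risk, sector, year, paf).
#' @param expenditures Expenditure table in 2014 dollars with sectors
#'   hospital, drugs, community, other.
#' @return Data frame (risk, sector, year, paf, expenditure, attributable,
#'   non_attributable) of class `burden_attribution`; attributable and
#'   non-attributable dollars sum to the expenditure exactly.
#' @export
attribute_expenditure <- function(pafs, expenditures) {
  if (!identical(attr(expenditures, "currency_year"), 2014))
    stop("expenditure table must be inflated to 2014 dollars first ",
         "(see inflate_expenditures)")
  stopifnot(all(c("risk", "sector", "year", "paf") %in% names(pafs)))
  years <- sort(unique(expenditures$fiscal_year))
  out <- list()
  for (r in unique(pafs$risk)) {
    pr <- pafs[pafs$risk == r, , drop = FALSE]
    for (s in unique(expenditures$sector)) {
      paf_sector <- if (s == "other") "community" else s
      ps <- pr[pr$sector == paf_sector, , drop = FALSE]
      for (y in years) {
        ex <- expenditures$amount[expenditures$sector == s &
                                  expenditures$fiscal_year == y]
        p <- ps$paf[ps$year == y]
        if (length(p) != 1L)
          stop("no PAF for (risk=", r, ", sector=", paf_sector,
               ", year=", y, ")")
        attributable <- p * ex
        out[[length(out) + 1L]] <- data.frame(
          risk = r, sector = s, year = y, paf = p,
          expenditure = ex, attributable = attributable,
          non_attributable = ex - attributable)
      }
    }
  }
  structure(do.call(rbind, out), class = c("burden_attribution", "data.frame"))
}

#' Avoided costs under a constant-baseline counterfactual
#'
#' Holds the baseline-year PAF fixed: the counterfactual budget is
#' C_t = B_t (1 - PAF_t) / (1 - PAF_0), i.e. the observed
#' non-attributable spending regrossed at the baseline attributable
#' share.  avoided(t) = C_t - B_t is positive exactly when PAF_t fell
#' below the baseline PAF.
#'
#' @param baseline_paf PAF in the baseline year (scalar < 1).
#' @param annual_pafs Named numeric vector of PAFs by year (< 1).
#' @param annual_budgets Named numeric vector of total budgets by year
#'   (2014 dollars), names matching `annual_pafs`.
#' @return Data frame (year, budget, paf, counterfactual_budget, avoided)
#'   with the cumulative total as attribute `cumulative`.
#' @export
avoided_costs <- function(baseline_paf, annual_pafs, annual_budgets) {
  if (baseline_paf >= 1 || any(annual_pafs >= 1))
    stop("PAF >= 1: counterfactual budget undefined")
  yrs <- names(annual_pafs)
  if (is.null(yrs) || !all(yrs %in% names(annual_budgets)))
    stop("annual_pafs and annual_budgets must share year names")
  b <- annual_budgets[yrs]
  cf <- b * (1 - annual_pafs) / (1 - baseline_paf)
  out <- data.frame(year = as.integer(yrs), budget = as.numeric(b),
                    paf = as.numeric(annual_pafs),
                    counterfactual_budget = as.numeric(cf),
                    avoided = as.numeric(cf - b))
  attr(out, "cumulative") <- sum(out$avoided)
  out
}

#' Summarize attributable and avoided burdens into shares
#'
#' Per-risk percentage of total attributable cost and of total avoided
#' cost (integer percent), plus sector shares of the attributable
#' burden.
#'
#' @param attribution A `burden_attribution` (single-risk rows only; the
#'   combined `behaviours`/`ses` rows are excluded from the share
#'   denominator).
#' @param avoided Named list risk -> [avoided_costs()] result (optional).
#' @return List with `risk_shares` (risk, attributable, attributable_pct,
#'   avoided, avoided_pct) and `sector_shares`.
#' @export
summarize_burden <- function(attribution, avoided = NULL) {
  single <- attribution[!attribution$risk %in% c("behaviours", "ses"), ,
                        drop = FALSE]
  tot_attr <- tapply(single$attributable, single$risk, sum)
  if (sum(tot_attr) == 0) {
    warning("total attributable cost is zero; shares undefined")
    pct_attr <- rep(NA_real_, length(tot_attr))
  } else pct_attr <- round(100 * tot_attr / sum(tot_attr))
  risk_shares <- data.frame(risk = names(tot_attr),
                            attributable = as.numeric(tot_attr),
                            attributable_pct = as.numeric(pct_attr))
  if (!is.null(avoided)) {
    av <- vapply(avoided, function(a) attr(a, "cumulative"), numeric(1))
    av <- av[risk_shares$risk]
    if (sum(av, na.rm = TRUE) == 0) {
      warning("total avoided cost is zero; shares undefined")
      pct_av <- rep(NA_real_, length(av))
    } else pct_av <- round(100 * av / sum(av, na.rm = TRUE))
    risk_shares$avoided <- as.numeric(av)
    risk_shares$avoided_pct <- as.numeric(pct_av)
  }
  sec <- tapply(single$attributable, single$sector, sum)
  sector_shares <- data.frame(sector = names(sec),
                              attributable = as.numeric(sec),
                              attributable_pct =
                                if (sum(sec) > 0) as.numeric(round(100 * sec / sum(sec)))
                                else NA_real_)
  list(risk_shares = risk_shares, sector_shares = sector_shares)
}
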