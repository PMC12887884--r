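## Binding-probability tables with binomial confidence intervals, and the
## interaction-energy-per-contact regression.

#' Binding percentage
#'
#' @param n_bound trajectories that reacted at the site.
#' @param n_total all trajectories (the full ensemble denominator).
#' @return percentage, `100 * n_bound / n_total`.
#' @export
binding_percent <- function(n_bound, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  stopifnot(all(n_bound >= 0), all(n_bound <= n_total))
  100 * n_bound / n_total
}

#' Binomial confidence half-width of a binding percentage
#'
#' One standard error of the observed binomial proportion,
#' `100 * sqrt(p (1 - p) / n)` with `p = n_bound / n_total`. This is the
#' convention that reproduces the printed +/- values of per-site binding
#' tables (e.g. 48,463 of 200,000 gives 24.2 +/- 0.1).
#'
#' @inheritParams binding_percent
#' @return half-width in percentage points.
#' @export
binomial_ci_halfwidth <- function(n_bound, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  p <- n_bound / n_total
  100 * sqrt(p * (1 - p) / n_total)
}

# decimals used for printing: the CI half-width is rounded to one
# significant figure and the percentage printed to the same number of
# decimal places (24.2 +/- 0.1, 10.50 +/- 0.07, 0.058 +/- 0.005)
.table_decimals <- function(ci) {
  ifelse(ci <= 0, 2L, pmax(0L, -floor(log10(signif(ci, 1))) ))
}

#' Per-site binding table
#'
#' One row per binding site (or configured composite site group):
#' reacted-trajectory count, bound percentage over the full trajectory
#' denominator, and the binomial confidence half-width.
#'
#' @param outcomes a [run_ensemble()] result (or any data frame with
#'   `status` and `site` columns).
#' @param sites residue numbers to report; defaults to every site that
#'   occurs plus, when available, the fibril site list recorded upstream.
#' @param site_groups optional named list of composite sites, e.g.
#'   `list("K317-K321" = c(317, 321))`; grouped residues are reported as
#'   one row with summed counts instead of individual rows.
#' @return object of class `site_table`: data frame with `site`,
#'   `n_bound`, `n_total`, `percent`, `ci_halfwidth`.
#' @export
site_table <- function(outcomes, sites = NULL, site_groups = NULL) {
  stopifnot(nrow(outcomes) >= 1)
  n_total <- nrow(outcomes)
  reacted <- outcomes[outcomes$status == "reacted", , drop = FALSE]
  if (is.null(sites)) sites <- sort(unique(reacted$site))
  grouped <- unlist(site_groups, use.names = FALSE)
  singles <- setdiff(sites, grouped)
  labels <- c(as.character(singles), names(site_groups))
  members <- c(as.list(singles), unname(site_groups))
  n_bound <- vapply(members, function(m) sum(reacted$site %in% m),
                    integer(1))
  tb <- data.frame(site = labels, n_bound = n_bound, n_total = n_total,
                   percent = binding_percent(n_bound, n_total),
                   ci_halfwidth = binomial_ci_halfwidth(n_bound, n_total))
  class(tb) <- c("site_table", "data.frame")
  tb
}

#' Format a site table at printed precision
#'
#' The confidence half-width is rounded to one significant figure and the
#' percentage is printed with the same number of decimals
#' (trailing-zero aware), the convention of per-site binding tables.
#'
#' @param tb a [site_table()].
#' @return data frame with character columns `site`, `n_bound`,
#'   `percent`, `ci`.
#' @export
format_site_table <- function(tb) {
  dec <- .table_decimals(tb$ci_halfwidth)
  data.frame(site = tb$site,
             n_bound = format(tb$n_bound, big.mark = ",", trim = TRUE),
             percent = vapply(seq_len(nrow(tb)), function(i)
               formatC(tb$percent[i], format = "f", digits = dec[i]),
               character(1)),
             ci = vapply(seq_len(nrow(tb)), function(i)
               formatC(signif(tb$ci_halfwidth[i], 1), format = "fg"),
               character(1)))
}

#' @export
print.site_table <- function(x, ...) {
  f <- format_site_table(x)
  cat("<site_table> denominator", x$n_total[1], "trajectories\n")
  print.data.frame(data.frame(site = f$site, bound = f$n_bound,
                              percent = paste0(f$percent, " +/- ", f$ci)),
                   row.names = FALSE)
  invisible(x)
}

#' Write a site table as TSV
#'
#' Columns mirror the printed table layout: residue, bound count, bound
#' percent, confidence half-width.
#'
#' @param tb a [site_table()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_site_table <- function(tb, path) {
  f <- format_site_table(tb)
  out <- data.frame(residue = f$site, heparin_bound_n = tb$n_bound,
                    heparin_bound_percent = f$percent, ci = f$ci)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Regression of interaction energy on contact count
#'
#' Ordinary least squares of pose energy (kcal/mol) on the number of
#' charged-group contacts, giving the stabilization per additional
#' contact as the slope.
#'
#' @param contact_counts integer vector of per-pose (or per-frame)
#'   contact counts.
#' @param energies matching energies, kcal/mol.
#' @return object of class `energy_regression`: `slope`, `slope_se`,
#'   `intercept`, `n_points`.
#' @export
energy_per_contact <- function(contact_counts, energies) {
  stopifnot(length(contact_counts) == length(energies),
            length(energies) >= 3)
  if (length(unique(contact_counts)) < 2)
    stop("all contact counts identical: slope undefined")
  fit <- lm(energies ~ contact_counts)
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(coef(fit)[2]),
                 slope_se = unname(sm[2, 2]),
                 intercept = unname(coef(fit)[1]),
                 n_points = length(energies)),
            class = "energy_regression")
}

#' @export
print.energy_regression <- function(x, ...) {
  cat("<energy_regression>", signif(x$slope, 3), "+/-",
      signif(x$slope_se, 2), "kcal/mol per contact (n =", x$n_points,
      ")\n")
  invisible(x)
}
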