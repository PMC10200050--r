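#' Read clip-cage assay records
#'
#' Reads a CSV with header
#' `species,accession,plant,cage,alive,dead,eggs_vhx7000,eggs_autoento`:
#' one row per clip-on cage of a no-choice whitefly assay (five females
#' released per cage for five days), with egg counts from each imaging
#' device. Rows where `alive + dead` differs from the number released are
#' kept with a warning — escaped or unrecovered whiteflies are a known
#' feature of clip-cage assays.
#'
#' @param path CSV path; defaults to the packaged assay dataset of four
#'   Solanum accessions (two susceptible cultivars, two resistant wild
#'   accessions; three plants per accession, two cages per plant).
#' @param released Number of whiteflies released per cage (default 5).
#' @return A data.frame of assay records with a `released` column.
#' @export
read_assay_records <- function(path = system.file("extdata",
                                                  "whitefly_assay.csv",
                                                  package = "eggquant"),
                               released = 5L) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "accession", "plant", "cage", "alive", "dead",
            "eggs_vhx7000", "eggs_autoento")
  if (!all(need %in% names(d))) {
    stop("assay CSV must have header ", paste(need, collapse = ","))
  }
  d$released <- as.integer(released)
  odd <- d$alive + d$dead != d$released
  if (any(odd)) {
    warning(sprintf("%d cage(s) with alive + dead != released (kept)",
                    sum(odd)))
  }
  stopifnot(all(d$alive >= 0), all(d$dead >= 0), all(d$released >= 1),
            all(d$eggs_vhx7000 >= 0), all(d$eggs_autoento >= 0))
  d
}

assay_devices <- c("vhx7000", "autoento")

#' Adult survival
#'
#' Fraction of released whiteflies alive at the end of the five-day
#' no-choice assay: `AS = alive / total`.
#'
#' @param alive Number of whiteflies alive, `<= total`.
#' @param total Number of whiteflies released (positive).
#' @return A value in `[0, 1]`.
#' @export
adult_survival <- function(alive, total) {
  stopifnot(all(total >= 1), all(alive >= 0))
  if (any(alive > total)) stop("alive exceeds total whiteflies")
  alive / total
}

#' Oviposition rate
#'
#' Eggs per female over the five-day assay, normalizing by the average of
#' the alive and released whiteflies:
#' `OR = 2 * eggs / (alive + total)` (eggs female^-1 per 5 days).
#'
#' @param eggs Egg count (non-negative).
#' @param alive Whiteflies alive at assay end, `<= total`.
#' @param total Whiteflies released (positive).
#' @return A non-negative rate.
#' @export
oviposition_rate <- function(eggs, alive, total) {
  stopifnot(all(eggs >= 0), all(total >= 1), all(alive >= 0))
  if (any(alive > total)) stop("alive exceeds total whiteflies")
  2 * eggs / (alive + total)
}

#' Per-plant assay summaries
#'
#' Pools the clip cages of each plant before applying the survival and
#' oviposition formulas (so each accession contributes its n = 3 plants,
#' not 6 cages, to the statistics): `AS = sum(alive) / sum(released)`,
#' `OR = 2 * sum(eggs) / (sum(alive) + sum(released))`. AS is normalized
#' with the arcsine-square-root transform and OR with the square-root
#' transform.
#'
#' @param records Assay records from [read_assay_records()].
#' @param device Which device's egg counts to use: `"vhx7000"` or
#'   `"autoento"`.
#' @return A data.frame with one row per plant: `species`, `accession`,
#'   `plant`, `AS`, `OR`, `transformed_AS`, `transformed_OR`.
#' @export
summarize_plants <- function(records, device = "vhx7000") {
  if (!device %in% assay_devices) {
    stop(sprintf("unknown device '%s'; available devices: %s", device,
                 paste(assay_devices, collapse = ", ")))
  }
  egg_col <- paste0("eggs_", device)
  key <- interaction(records$accession, records$plant, drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    alive <- sum(g$alive)
    released <- sum(g$released)
    eggs <- sum(g[[egg_col]])
    data.frame(species = g$species[1], accession = g$accession[1],
               plant = g$plant[1],
               AS = adult_survival(alive, released),
               OR = oviposition_rate(eggs, alive, released),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$accession, out$plant), ]
  rownames(out) <- NULL
  out$transformed_AS <- asin(sqrt(out$AS))
  out$transformed_OR <- sqrt(out$OR)
  out
}

#' Compare two accessions on a transformed assay metric
#'
#' Two-sample, two-sided t-test on the transformed per-plant values
#' (arcsine-square-root AS or square-root OR). The equal-variance
#' Student's test is the default; Welch's is available via
#' `var_equal = FALSE`.
#'
#' @param summaries A [summarize_plants()] data.frame.
#' @param accession_a,accession_b Accession names present in `summaries`.
#' @param metric `"AS"` or `"OR"`.
#' @param var_equal Use the pooled-variance Student's test (default).
#' @return A one-row data.frame: accessions, metric, group sizes and
#'   means (transformed scale), `t`, `p`, and significance flags at the
#'   0.05, 0.01 and 0.001 levels.
#' @export
compare_accessions <- function(summaries, accession_a, accession_b,
                               metric = c("AS", "OR"), var_equal = TRUE) {
  metric <- match.arg(metric)
  col <- paste0("transformed_", metric)
  a <- summaries[[col]][summaries$accession == accession_a]
  b <- summaries[[col]][summaries$accession == accession_b]
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 plants per accession")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      stop("zero within-group variance in both groups: ",
           "a t-test is degenerate; compare the groups exactly")
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
  }
  p <- tt$p.value
  data.frame(accession_a = accession_a, accession_b = accession_b,
             metric = metric, n_a = length(a), n_b = length(b),
             mean_a = mean(a), mean_b = mean(b),
             t = unname(tt$statistic), p = p,
             sig_0.05 = p < 0.05, sig_0.01 = p < 0.01,
             sig_0.001 = p < 0.001, stringsAsFactors = FALSE)
}

#' Default susceptible-vs-resistant comparison plan
#'
#' Pairs each susceptible cultivar with the resistant wild accession of
#' the same crop: tomato Moneymaker vs LA1777 and potato RH89-039-16 vs
#' BER481-3.
#'
#' @return A data.frame with columns `susceptible`, `resistant`.
#' @export
default_comparison_plan <- function() {
  data.frame(susceptible = c("Moneymaker", "RH89-039-16"),
             resistant = c("LA1777", "BER481-3"),
             stringsAsFactors = FALSE)
}

#' Resistance/susceptibility report
#'
#' For each susceptible/resistant accession pair in the plan, compares
#' adult survival and oviposition rate (transformed scales) between the
#' accessions' plants.
#'
#' @param records Assay records ([read_assay_records()]).
#' @param device Egg-count device (`"vhx7000"` or `"autoento"`); AS does
#'   not depend on it.
#' @param plan A comparison plan data.frame (columns `susceptible`,
#'   `resistant`); default [default_comparison_plan()].
#' @param var_equal Passed to [compare_accessions()].
#' @return A `resistance_report` list: `summaries` (per-plant table) and
#'   `comparisons` (one row per pair and metric).
#' @export
resistance_report <- function(records, device = "vhx7000",
                              plan = default_comparison_plan(),
                              var_equal = TRUE) {
  summaries <- summarize_plants(records, device)
  missing <- setdiff(unique(c(plan$susceptible, plan$resistant)),
                     unique(summaries$accession))
  if (length(missing)) {
    stop("accession(s) absent from records: ",
         paste(missing, collapse = ", "))
  }
  comps <- list()
  for (i in seq_len(nrow(plan))) {
    for (metric in c("AS", "OR")) {
      comps[[length(comps) + 1L]] <- compare_accessions(
        summaries, plan$susceptible[i], plan$resistant[i], metric,
        var_equal = var_equal)
    }
  }
  comparisons <- if (length(comps)) do.call(rbind, comps) else
    data.frame()
  structure(list(summaries = summaries, comparisons = comparisons,
                 device = device),
            class = "resistance_report")
}

#' @export
print.resistance_report <- function(x, ...) {
  cat(sprintf("resistance report (device %s)\n", x$device))
  if (nrow(x$comparisons)) {
    df <- x$comparisons
    cat(sprintf("  %s vs %s  %s: t = %.3f, p = %.4g%s\n",
                df$accession_a, df$accession_b, df$metric, df$t, df$p,
                ifelse(df$sig_0.05, " *", "")), sep = "")
  }
  invisible(x)
}
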