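# 28-day regimen drug-cost model: dosing lines (flat mg or mg/kg at a fixed
# administration interval, optionally phase-limited) are expanded to an
# administration calendar over a half-open day window and priced per mg.

#' Build one regimen dosing line
#'
#' A drug given at `dose_value` mg (or mg/kg when `per_kg`) every
#' `interval_days` days, starting on `phase_start_day` (day 0 is the first
#' administration) and ending before `phase_end_day` (`Inf` for open-ended).
#'
#' @param drug_name Drug label (matched against the price table).
#' @param dose_value Dose in mg, or mg/kg when `per_kg = TRUE` (> 0).
#' @param per_kg Whether the dose scales with body weight.
#' @param interval_days Days between administrations (>= 1; 1 = daily).
#' @param phase_start_day,phase_end_day Half-open phase window in days.
#' @return A one-row tibble.
#' @examples
#' regimen_line("pazopanib", 800) # 800 mg daily, open-ended
#' regimen_line("nivolumab", 3, per_kg = TRUE, interval_days = 14)
#' @export
regimen_line <- function(drug_name, dose_value, per_kg = FALSE,
                         interval_days = 1, phase_start_day = 0,
                         phase_end_day = Inf) {
  if (!is.numeric(dose_value) || dose_value <= 0) {
    stop_oncovalue("`dose_value` must be > 0.")
  }
  if (!is.numeric(interval_days) || interval_days < 1) {
    stop_oncovalue("`interval_days` must be >= 1.")
  }
  if (phase_end_day <= phase_start_day) {
    stop_oncovalue("`phase_end_day` must exceed `phase_start_day`.")
  }
  tibble(
    drug_name = as.character(drug_name),
    dose_value = as.double(dose_value),
    per_kg = isTRUE(per_kg),
    interval_days = as.double(interval_days),
    phase_start_day = as.double(phase_start_day),
    phase_end_day = as.double(phase_end_day)
  )
}

#' Assemble a regimen schedule
#'
#' @param name Regimen label.
#' @param ... One-row tibbles from [regimen_line()].
#' @return A tibble of dosing lines with a `regimen` attribute; phases of
#'   the same drug must not overlap.
#' @examples
#' regimen_schedule(
#'   "cabozantinib + nivolumab",
#'   regimen_line("cabozantinib", 40),
#'   regimen_line("nivolumab", 240, interval_days = 14)
#' )
#' @export
regimen_schedule <- function(name, ...) {
  lines <- bind_rows(...)
  split_lines <- split(lines, lines$drug_name)
  for (dl in split_lines) {
    if (nrow(dl) > 1) {
      dl <- dl[order(dl$phase_start_day), ]
      if (any(dl$phase_end_day[-nrow(dl)] > dl$phase_start_day[-1])) {
        stop_oncovalue(sprintf(
          "Phases for drug `%s` overlap.", dl$drug_name[1]
        ))
      }
    }
  }
  attr(lines, "regimen") <- as.character(name)
  lines
}

#' Expand a regimen to per-drug milligram totals over a window
#'
#' Administrations fall on days `phase_start_day, phase_start_day +
#' interval_days, ...` strictly before `phase_end_day`; the half-open
#' window `[start, end)` counts an administration if its day lies inside.
#' Per-kg doses are multiplied by the body weight.
#'
#' @param schedule A [regimen_schedule()].
#' @param weight_kg Body weight in kg (> 0).
#' @param window Numeric length-2, half-open day window (default the 28-day
#'   month `c(0, 28)`).
#' @return A tibble with one row per drug: `drug_name`, `n_administrations`,
#'   `total_mg`.
#' @examples
#' expand_doses(regimen_schedule("p", regimen_line("pazopanib", 800)), 60)
#' @export
expand_doses <- function(schedule, weight_kg, window = c(0, 28)) {
  if (!is.numeric(weight_kg) || weight_kg <= 0) {
    stop_oncovalue("`weight_kg` must be > 0.")
  }
  if (length(window) != 2 || window[2] < window[1]) {
    stop_oncovalue("`window` must be an ordered pair of days.")
  }
  per_line <- lapply(seq_len(nrow(schedule)), function(i) {
    ln <- schedule[i, ]
    lo <- max(window[1], ln$phase_start_day)
    hi <- min(window[2], ln$phase_end_day)
    if (hi <= lo) {
      n_adm <- 0
    } else {
      # administration days: phase_start_day + k * interval_days in [lo, hi)
      k_min <- ceiling((lo - ln$phase_start_day) / ln$interval_days)
      k_max <- ceiling((hi - ln$phase_start_day) / ln$interval_days) - 1
      n_adm <- max(0, k_max - k_min + 1)
    }
    mg_each <- ln$dose_value * if (ln$per_kg) weight_kg else 1
    tibble(
      drug_name = ln$drug_name,
      n_administrations = as.integer(n_adm),
      total_mg = n_adm * mg_each
    )
  })
  list_rbind(per_line) |>
    group_by(.data$drug_name) |>
    summarise(
      n_administrations = sum(.data$n_administrations),
      total_mg = sum(.data$total_mg),
      .groups = "drop"
    )
}

#' Read a drug price table from CSV
#'
#' Columns: `drug_name`, `price_per_mg`, `currency`. Prices must be
#' non-negative.
#'
#' @param path Path to the CSV file.
#' @return A price tibble.
#' @export
read_prices <- function(path) {
  prices <- readr::read_csv(
    path,
    col_types = readr::cols(
      drug_name = readr::col_character(),
      price_per_mg = readr::col_double(),
      currency = readr::col_character()
    )
  )
  if (any(prices$price_per_mg < 0)) {
    stop_oncovalue("Prices must be >= 0.")
  }
  prices
}

#' Drug cost of a regimen over a 28-day month
#'
#' Expands the schedule with [expand_doses()] and prices the milligram
#' totals. Vial rounding is not modelled: costs are exact-mg.
#'
#' @param schedule A [regimen_schedule()].
#' @param prices A price tibble (see [read_prices()]).
#' @param weight_kg Body weight in kg (default 60).
#' @param window Half-open day window (default `c(0, 28)`).
#' @return Total cost (currency units of the price table) with the per-drug
#'   breakdown attached as attribute `"breakdown"`.
#' @examples
#' sched <- regimen_schedule("p", regimen_line("pazopanib", 800))
#' prices <- tibble::tibble(
#'   drug_name = "pazopanib",
#'   price_per_mg = 0.5, currency = "USD"
#' )
#' monthly_cost(sched, prices) # 22400 mg * 0.5
#' @export
monthly_cost <- function(schedule, prices, weight_kg = 60, window = c(0, 28)) {
  doses <- expand_doses(schedule, weight_kg, window)
  unpriced <- setdiff(doses$drug_name, prices$drug_name)
  if (length(unpriced) > 0) {
    stop_oncovalue(sprintf(
      "No price for drug(s): %s.", paste(unpriced, collapse = ", ")
    ))
  }
  breakdown <- doses |>
    left_join(prices[c("drug_name", "price_per_mg")], by = "drug_name") |>
    mutate(cost = .data$total_mg * .data$price_per_mg)
  total <- sum(breakdown$cost)
  attr(total, "breakdown") <- breakdown
  total
}

#' Fixture regimens for the six RCC comparisons
#'
#' The treatment-arm dosing schedules as published: pazopanib 800 mg daily;
#' nivolumab 3 mg/kg + ipilimumab 1 mg/kg every 2 weeks for the first 12
#' weeks then nivolumab 3 mg/kg every 2 weeks; axitinib 5 mg daily with
#' avelumab 10 mg/kg every 3 weeks or pembrolizumab 200 mg every 3 weeks;
#' lenvatinib 20 mg daily + pembrolizumab 200 mg every 3 weeks; cabozantinib
#' 40 mg daily + nivolumab 240 mg every 2 weeks.
#'
#' @return A named list of [regimen_schedule()] objects.
#' @export
rcc_regimens <- function() {
  list(
    pazopanib = regimen_schedule(
      "pazopanib",
      regimen_line("pazopanib", 800)
    ),
    nivolumab_ipilimumab = regimen_schedule(
      "nivolumab + ipilimumab",
      regimen_line("nivolumab", 3,
        per_kg = TRUE, interval_days = 14,
        phase_start_day = 0, phase_end_day = 84
      ),
      regimen_line("ipilimumab", 1,
        per_kg = TRUE, interval_days = 14,
        phase_start_day = 0, phase_end_day = 84
      ),
      regimen_line("nivolumab", 3,
        per_kg = TRUE, interval_days = 14,
        phase_start_day = 84
      )
    ),
    axitinib_avelumab = regimen_schedule(
      "axitinib + avelumab",
      regimen_line("axitinib", 5),
      regimen_line("avelumab", 10, per_kg = TRUE, interval_days = 21)
    ),
    axitinib_pembrolizumab = regimen_schedule(
      "axitinib + pembrolizumab",
      regimen_line("axitinib", 5),
      regimen_line("pembrolizumab", 200, interval_days = 21)
    ),
    lenvatinib_pembrolizumab = regimen_schedule(
      "lenvatinib + pembrolizumab",
      regimen_line("lenvatinib", 20),
      regimen_line("pembrolizumab", 200, interval_days = 21)
    ),
    cabozantinib_nivolumab = regimen_schedule(
      "cabozantinib + nivolumab",
      regimen_line("cabozantinib", 40),
      regimen_line("nivolumab", 240, interval_days = 14)
    )
  )
}

#' Per-regimen 28-day cost report
#'
#' @param regimens A named list of [regimen_schedule()] objects
#'   (default [rcc_regimens()]).
#' @param prices A price tibble; the shipped default is a synthetic price
#'   list (`inst/extdata/prices_synthetic.csv`) because published unit
#'   prices are not available.
#' @param weight_kg Body weight in kg (default 60).
#' @param window Half-open day window (default `c(0, 28)`).
#' @return A tibble: `regimen`, `cost`, plus per-drug breakdown in a
#'   list-column.
#' @export
cost_report <- function(regimens = rcc_regimens(),
                        prices = read_prices(system.file("extdata",
                          "prices_synthetic.csv",
                          package = "oncovalue", mustWork = TRUE
                        )),
                        weight_kg = 60, window = c(0, 28)) {
  rows <- imap(regimens, function(sched, nm) {
    total <- monthly_cost(sched, prices, weight_kg, window)
    tibble(
      regimen = attr(sched, "regimen") %||% nm,
      cost = round(as.numeric(total), 2),
      breakdown = list(attr(total, "breakdown"))
    )
  })
  list_rbind(unname(rows))
}
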