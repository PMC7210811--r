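#' Read and validate germination scoring records
#'
#' The CSV dialect has one row per dish x observation day with columns
#' `site, pretreatment_days, temperature_c, dish, day, cum_germinated,
#' sown, empty, viable_ungerminated`; the end-of-test cut-test counts
#' (`sown`, `empty`, `viable_ungerminated`) are repeated on every row of a
#' dish. Validation enforces, per dish: observation days strictly
#' increasing, cumulative counts non-decreasing, all counts non-negative,
#' and the cut-test accounting identity
#' `final cum_germinated + empty + viable_ungerminated = sown`.
#'
#' @param path Path to a germination CSV.
#' @return A validated long-format data.frame of records.
#' @export
read_germination_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("site", "pretreatment_days", "temperature_c", "dish", "day",
              "cum_germinated", "sown", "empty", "viable_ungerminated")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("germination CSV is missing columns: ",
         paste(missing, collapse = ", "))
  df$line <- seq_len(nrow(df)) + 1L  # header is line 1
  validate_germination_records(df)
  df$line <- NULL
  df
}

#' Write germination records in the package CSV dialect
#'
#' @param records Long-format germination records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_germination_records <- function(records, path) {
  cols <- c("site", "pretreatment_days", "temperature_c", "dish", "day",
            "cum_germinated", "sown", "empty", "viable_ungerminated")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

dish_key <- function(records) {
  interaction(records$site, records$pretreatment_days,
              records$temperature_c, records$dish, drop = TRUE)
}

#' Validate germination record invariants
#'
#' @param records Long-format germination records (see
#'   [read_germination_records()] for the dialect).
#' @return `records`, invisibly; stops with a message naming the dish (and
#'   line numbers when a `line` column is present) on the first violation.
#' @export
validate_germination_records <- function(records) {
  counts <- c("pretreatment_days", "day", "cum_germinated", "sown",
              "empty", "viable_ungerminated")
  for (col in counts)
    if (any(records[[col]] < 0))
      stop("negative values in column '", col, "'",
           line_hint(records, records[[col]] < 0))
  for (key in levels(dish_key(records))) {
    d <- records[dish_key(records) == key, ]
    label <- paste0("dish ", d$site[1], "/C", d$pretreatment_days[1], "/",
                    d$temperature_c[1], "C/#", d$dish[1])
    if (length(unique(d$sown)) != 1 || length(unique(d$empty)) != 1 ||
        length(unique(d$viable_ungerminated)) != 1)
      stop(label, ": end-of-test counts must be constant within a dish")
    if (any(diff(d$day) <= 0))
      stop(label, ": observation days must be strictly increasing")
    if (any(diff(d$cum_germinated) < 0))
      stop(label, ": cumulative counts must be non-decreasing")
    final <- d$cum_germinated[nrow(d)]
    if (final + d$empty[1] + d$viable_ungerminated[1] != d$sown[1])
      stop(label, ": accounting identity violated (final ", final,
           " + empty ", d$empty[1], " + viable ", d$viable_ungerminated[1],
           " != sown ", d$sown[1], ")", line_hint(records,
           dish_key(records) == key))
  }
  invisible(records)
}

line_hint <- function(records, which_rows) {
  if (!"line" %in% names(records)) return("")
  paste0(" [lines ", paste(utils::head(records$line[which_rows], 5),
                           collapse = ", "), "]")
}

#' Per-dish end-of-test summary
#'
#' Collapses long-format records to one row per dish, with the filled-seed
#' count (`sown - empty`) and the final germination percentage on the
#' filled-seed basis (`NA` where a dish has no filled seeds).
#'
#' @param records Long-format germination records.
#' @return A data.frame with one row per dish: `site`, `pretreatment_days`,
#'   `temperature_c`, `dish`, `sown`, `empty`, `filled`, `germinated`,
#'   `viable_ungerminated`, `pct`.
#' @export
per_dish_summary <- function(records) {
  keys <- dish_key(records)
  rows <- lapply(levels(keys), function(key) {
    d <- records[keys == key, ]
    d <- d[order(d$day), ]
    filled <- d$sown[1] - d$empty[1]
    germ <- d$cum_germinated[nrow(d)]
    data.frame(site = d$site[1], pretreatment_days = d$pretreatment_days[1],
               temperature_c = d$temperature_c[1], dish = d$dish[1],
               sown = d$sown[1], empty = d$empty[1], filled = filled,
               germinated = germ,
               viable_ungerminated = d$viable_ungerminated[1],
               pct = if (filled > 0) 100 * germ / filled else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$site, out$pretreatment_days, out$temperature_c,
                   out$dish), ]
  rownames(out) <- NULL
  out
}

#' Final germination percentage per condition
#'
#' For each site x pretreatment x temperature condition, the final
#' germination percentage is computed per dish on the filled-seed basis
#' (`100 * germinated / (sown - empty)`) and summarised as mean and sample
#' SD (n - 1) across dishes. Dishes with no filled seeds are excluded with
#' a message; a condition where every dish has zero filled seeds is an
#' error.
#'
#' @param records Long-format germination records (any number of
#'   conditions).
#' @return A data.frame with one row per condition: `site`,
#'   `pretreatment_days`, `temperature_c`, `n_dishes`, `mean_pct`,
#'   `sd_pct`.
#' @export
final_germination <- function(records) {
  s <- per_dish_summary(records)
  cond <- interaction(s$site, s$pretreatment_days, s$temperature_c,
                      drop = TRUE)
  rows <- lapply(levels(cond), function(key) {
    d <- s[cond == key, ]
    bad <- d$filled == 0
    if (all(bad))
      stop("condition ", d$site[1], "/C", d$pretreatment_days[1], "/",
           d$temperature_c[1],
           "C: all dishes have zero filled seeds; percentage undefined")
    if (any(bad)) {
      message("excluding ", sum(bad), " dish(es) with zero filled seeds in ",
              d$site[1], "/C", d$pretreatment_days[1], "/",
              d$temperature_c[1], "C")
      d <- d[!bad, ]
    }
    data.frame(site = d$site[1], pretreatment_days = d$pretreatment_days[1],
               temperature_c = d$temperature_c[1], n_dishes = nrow(d),
               mean_pct = mean(d$pct),
               sd_pct = if (nrow(d) > 1) stats::sd(d$pct) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$site, out$pretreatment_days, out$temperature_c), ]
  rownames(out) <- NULL
  out
}

#' Pooled cumulative germination curve for one condition
#'
#' Pools the replicate dishes of one site x pretreatment x temperature
#' condition into a single cumulative germination curve, expressed as a
#' fraction of the pooled filled seeds (default), of the viable seeds
#' (`germinated + viable_ungerminated`; identical to the filled basis
#' whenever the cut-test accounting identity holds), or of the seeds that
#' eventually germinated (so the curve ends at 1 and percentiles are "of
#' final germination attained"). Dishes on different observation
#' schedules are merged on the union of observation days with each dish's
#' last count carried forward.
#'
#' @param records Long-format germination records.
#' @param site,pretreatment_days,temperature_c Condition key; may be
#'   omitted when `records` holds a single condition.
#' @param basis Denominator basis: `"filled"` (sown - empty), `"viable"`
#'   (germinated + viable ungerminated) or `"germinated"` (final
#'   germinated count).
#' @return An object of class `"germination_curve"`: a list with the
#'   condition key, `day`, `cum_fraction` (non-decreasing, <= 1),
#'   `denominator`, and `final_fraction`.
#' @export
pool_curve <- function(records, site = NULL, pretreatment_days = NULL,
                       temperature_c = NULL,
                       basis = c("filled", "viable", "germinated")) {
  basis <- match.arg(basis)
  sel <- rep(TRUE, nrow(records))
  if (!is.null(site)) sel <- sel & records$site == site
  if (!is.null(pretreatment_days))
    sel <- sel & records$pretreatment_days == pretreatment_days
  if (!is.null(temperature_c))
    sel <- sel & records$temperature_c == temperature_c
  d <- records[sel, ]
  if (nrow(d) == 0) stop("no records match the requested condition")
  cond <- unique(d[, c("site", "pretreatment_days", "temperature_c")])
  if (nrow(cond) != 1)
    stop("records span ", nrow(cond),
         " conditions; specify site, pretreatment_days and temperature_c")

  keys <- dish_key(d)
  days <- sort(unique(d$day))
  cum_total <- numeric(length(days))
  denom <- 0
  for (key in levels(keys)) {
    dd <- d[keys == key, ]
    dd <- dd[order(dd$day), ]
    denom <- denom + switch(basis,
      filled = dd$sown[1] - dd$empty[1],
      viable = dd$cum_germinated[nrow(dd)] + dd$viable_ungerminated[1],
      germinated = dd$cum_germinated[nrow(dd)])
    # last observation carried forward onto the union time axis
    idx <- findInterval(days, dd$day)
    cum_total <- cum_total + c(0, dd$cum_germinated)[idx + 1]
  }
  if (denom <= 0)
    stop("condition ", cond$site, "/C", cond$pretreatment_days, "/",
         cond$temperature_c, "C: zero ", basis, " seeds; curve undefined")
  structure(list(site = cond$site,
                 pretreatment_days = cond$pretreatment_days,
                 temperature_c = cond$temperature_c,
                 day = days, cum_fraction = cum_total / denom,
                 denominator = denom, basis = basis,
                 final_fraction = cum_total[length(days)] / denom),
            class = "germination_curve")
}

#' @export
print.germination_curve <- function(x, ...) {
  cat("Germination curve ", x$site, "/C", x$pretreatment_days, "/",
      x$temperature_c, " degC (", x$basis, " basis, n = ", x$denominator,
      ")\n", sep = "")
  cat("  final germination: ",
      formatC(100 * x$final_fraction, format = "f", digits = 2),
      "% over ", length(x$day), " observation days (last day ",
      max(x$day), ")\n", sep = "")
  invisible(x)
}
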