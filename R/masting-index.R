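#' Column dialect for ordinal masting record files
#'
#' Masting archives store one ordinal seed-crop observation per row. The
#' default dialect matches the MASTREE-style layout (five-class ordinal
#' column named `ORDmast`); any CSV with equivalent columns can be mapped by
#' overriding individual entries.
#'
#' @param series_id,region,species,year,ord_class,proxy Column names in the
#'   file holding, respectively: the series identifier, the NUTS-1 (or
#'   synthetic) region code, the species label, the calendar year, the
#'   ordinal masting class (1 = very poor ... 5 = very abundant), and the
#'   observation proxy (e.g. `"seed"`, `"pollen"`, `"flowering"`, `"dendro"`).
#' @return A named character vector mapping internal names to file columns.
#' @export
#' @examples
#' mastree_dialect()
#' mastree_dialect(region = "NUTS_1")
mastree_dialect <- function(series_id = "SeriesID", region = "NUTS1",
                            species = "Species", year = "Year",
                            ord_class = "ORDmast", proxy = "Proxy") {
  c(series_id = series_id, region = region, species = species,
    year = year, ord_class = ord_class, proxy = proxy)
}

#' Read ordinal masting records from a CSV file
#'
#' Parses a MASTREE-dialect CSV into a tidy record table. Rows whose ordinal
#' class falls outside 1--5 (or cannot be parsed) are excluded and reported
#' via the `"rejected"` attribute and a message.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Column mapping, see [mastree_dialect()].
#' @return A tibble with columns `series_id`, `region`, `species`, `year`,
#'   `ord_class`, `proxy`. Rejected rows (if any) are attached as the
#'   `"rejected"` attribute.
#' @export
read_mast_records <- function(path, dialect = mastree_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble(
    series_id = as.character(raw[[dialect[["series_id"]]]]),
    region    = as.character(raw[[dialect[["region"]]]]),
    species   = as.character(raw[[dialect[["species"]]]]),
    year      = raw[[dialect[["year"]]]],
    ord_class = raw[[dialect[["ord_class"]]]],
    proxy     = as.character(raw[[dialect[["proxy"]]]])
  )
  if (nrow(out) == 0) {
    attr(out, "rejected") <- out
    return(out)
  }
  year_num <- suppressWarnings(as.numeric(out$year))
  if (anyNA(year_num)) stop("unparseable year values in ", path, call. = FALSE)
  out$year <- as.integer(year_num)
  cls <- suppressWarnings(as.numeric(out$ord_class))
  ok <- is.finite(cls) & cls == round(cls) & cls >= 1 & cls <= 5
  rejected <- out[!ok, , drop = FALSE]
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " record(s) with ordinal class outside 1-5 excluded")
  }
  out <- out[ok, , drop = FALSE]
  out$ord_class <- as.integer(cls[ok])
  attr(out, "rejected") <- rejected
  out
}

#' Filter masting records by year, proxy and region
#'
#' Applies the record-selection rules used for continental masting analyses:
#' truncate to a final year, drop unwanted observation proxies (e.g. pollen
#' and flowering), and optionally restrict to a region whitelist.
#'
#' @param records Record tibble as returned by [read_mast_records()].
#' @param max_year Keep records with `year <= max_year` (default no cutoff).
#' @param excluded_proxies Character vector of proxy labels to drop.
#' @param region_whitelist Optional character vector; if supplied (even
#'   empty), only records whose region is listed are kept.
#' @return Filtered record tibble; an empty result is allowed.
#' @export
filter_mast_records <- function(records, max_year = Inf,
                                excluded_proxies = character(),
                                region_whitelist = NULL) {
  out <- dplyr::filter(records, .data$year <= max_year,
                       !(.data$proxy %in% excluded_proxies))
  if (!is.null(region_whitelist)) {
    out <- dplyr::filter(out, .data$region %in% region_whitelist)
  }
  out
}

#' Aggregate record series into regional modal chronologies
#'
#' To avoid oversampling regions holding many series, observations are
#' collapsed to one value per (region, year): the statistical mode of the
#' ordinal class across that region's series. Ties are broken toward the
#' lowest tied class, a deterministic rule that is conservative about
#' declaring mast years. Region-years with no observation are simply absent.
#'
#' @param records Validated record tibble.
#' @return A tibble with columns `region`, `year`, `modal_class`, `n_series`.
#' @export
#' @examples
#' recs <- tibble::tibble(series_id = c("a", "b", "c"), region = "R1",
#'                        species = "sp", year = 2000,
#'                        ord_class = c(3L, 4L, 4L), proxy = "seed")
#' aggregate_modal(recs)  # modal class 4
aggregate_modal <- function(records) {
  records %>%
    group_by(.data$region, .data$year) %>%
    summarise(modal_class = modal_class(.data$ord_class),
              n_series = dplyr::n_distinct(.data$series_id),
              .groups = "drop") %>%
    arrange(.data$region, .data$year)
}

#' Compute the annual continental masting synchrony index
#'
#' For each year, over the regions with a modal class that year, the index is
#' `m = nc45 - nc12`: the proportion of regions in the good-mast classes 4-5
#' minus the proportion in the poor-mast classes 1-2. It runs from -1 (all
#' regions fail simultaneously) to +1 (all regions mast synchronously); zero
#' indicates prevalence of class 3 or a balanced split. The number of
#' contributing regions may differ between years; years with fewer than
#' `min_regions` contributing regions get a missing index, never zero.
#'
#' @param chronologies Output of [aggregate_modal()].
#' @param years Optional integer vector of years to report (default: all
#'   years present in `chronologies`).
#' @param min_regions Minimum number of contributing regions required for a
#'   year to receive a value (default 1).
#' @return A tibble of class `mast_index` with columns `year`, `m`, `nc45`,
#'   `nc12`, `n_regions`.
#' @export
compute_m_index <- function(chronologies, years = NULL, min_regions = 1L) {
  per_year <- chronologies %>%
    dplyr::filter(!is.na(.data$modal_class)) %>%
    group_by(.data$year) %>%
    summarise(
      nc45 = mean(.data$modal_class >= 4L),
      nc12 = mean(.data$modal_class <= 2L),
      n_regions = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(m = .data$nc45 - .data$nc12)
  if (is.null(years)) years <- sort(unique(per_year$year))
  out <- tibble(year = as.integer(years)) %>%
    left_join(per_year, by = "year") %>%
    mutate(
      drop = is.na(.data$n_regions) | .data$n_regions < min_regions,
      m = ifelse(.data$drop, NA_real_, .data$m),
      nc45 = ifelse(.data$drop, NA_real_, .data$nc45),
      nc12 = ifelse(.data$drop, NA_real_, .data$nc12),
      n_regions = ifelse(is.na(.data$n_regions), 0L, .data$n_regions)
    ) %>%
    select("year", "m", "nc45", "nc12", "n_regions")
  class(out) <- c("mast_index", class(out))
  out
}

#' Rescale a [-1, 1] masting index to the open unit interval
#'
#' Maps `m` in \[-1, 1\] to (0, 1) for use as a beta-distributed response:
#' first the affine map `y = (m + 1) / 2`, then the Smithson-Verkuilen
#' boundary compression `y' = (y * (n - 1) + 0.5) / n`, which pulls exact 0s
#' and 1s strictly inside the interval. The compression length `n` defaults
#' to the number of non-missing values and is stored for inversion.
#'
#' @param m Numeric vector in \[-1, 1\].
#' @param n Compression sample size (default `sum(!is.na(m))`).
#' @return Numeric vector in (0, 1) with attribute `"n"`.
#' @seealso [unscale_unit()] for the inverse map.
#' @export
#' @examples
#' rescale_unit(c(-1, 0, 1), n = 100)
rescale_unit <- function(m, n = sum(!is.na(m))) {
  if (any(m < -1 - 1e-12 | m > 1 + 1e-12, na.rm = TRUE)) {
    stop("masting index values must lie in [-1, 1]", call. = FALSE)
  }
  y <- (m + 1) / 2
  out <- (y * (n - 1) + 0.5) / n
  attr(out, "n") <- n
  out
}

#' Invert the unit-interval rescaling back to the masting-index scale
#'
#' @param y Numeric vector in (0, 1) as produced by [rescale_unit()].
#' @param n Compression sample size; taken from the `"n"` attribute when
#'   present.
#' @return Numeric vector on the \[-1, 1\] masting-index scale.
#' @export
unscale_unit <- function(y, n = attr(y, "n")) {
  if (is.null(n)) stop("compression size n not supplied", call. = FALSE)
  2 * ((as.numeric(y) * n - 0.5) / (n - 1)) - 1
}

#' Write a masting index series to a tidy CSV
#'
#' @param m_index A `mast_index` tibble from [compute_m_index()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_m_index <- function(m_index, path) {
  readr::write_csv(as_tibble(m_index), path, progress = FALSE)
  invisible(path)
}
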