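make_records <- function(region, year, classes) {
  tibble::tibble(
    series_id = paste0(region, "_S", seq_along(classes)),
    region = region, species = "sp", year = year,
    ord_class = as.integer(classes), proxy = "seed"
  )
}

test_that("reader validates ordinal classes and reports rejects", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SeriesID,NUTS1,Species,Year,ORDmast,Proxy",
               "s1,DE1,beech,2000,3,seed",
               "s2,DE1,beech,2000,6,seed",
               "s3,DE2,beech,2001,5,pollen"), path)
  expect_message(rec <- read_mast_records(path), "excluded")
  expect_equal(nrow(rec), 2L)
  expect_equal(nrow(attr(rec, "rejected")), 1L)
  expect_setequal(rec$ord_class, c(3L, 5L))
})

test_that("reader handles empty files and missing columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("SeriesID,NUTS1,Species,Year,ORDmast,Proxy", path)
  expect_equal(nrow(read_mast_records(path)), 0L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SeriesID,Year", "s1,2000"), bad)
  expect_error(read_mast_records(bad), "missing mandatory columns")
})

test_that("record filters apply the cutoff, proxy and whitelist rules", {
  rec <- tibble::tibble(
    series_id = paste0("s", 1:4), region = c("DE1", "DE1", "FR1", "SE1"),
    species = "sp", year = c(2014L, 2015L, 2010L, 2012L),
    ord_class = c(3L, 4L, 2L, 5L),
    proxy = c("seed", "seed", "pollen", "flowering")
  )
  expect_equal(filter_mast_records(rec, max_year = 2014)$year, c(2014L, 2010L, 2012L))
  out <- filter_mast_records(rec, excluded_proxies = c("pollen", "flowering"))
  expect_true(all(!out$proxy %in% c("pollen", "flowering")))
  expect_equal(nrow(filter_mast_records(rec, region_whitelist = character())), 0L)
  expect_equal(filter_mast_records(rec, region_whitelist = "FR1")$region, "FR1")
})

test_that("modal aggregation uses the mode with lowest-tied-class rule", {
  expect_equal(aggregate_modal(make_records("R1", 2000, c(3, 4, 4)))$modal_class, 4L)
  expect_equal(aggregate_modal(make_records("R1", 2000, c(2, 2, 4, 4)))$modal_class, 2L)
  expect_equal(aggregate_modal(make_records("R1", 2000, 5))$modal_class, 5L)
})

test_that("index formula matches its defining proportions on small cases", {
  chron_of <- function(classes) {
    tibble::tibble(region = paste0("R", seq_along(classes)),
                   year = 2000L, modal_class = as.integer(classes),
                   n_series = 1L)
  }
  expect_equal(compute_m_index(chron_of(c(5, 5, 5)))$m, 1)
  mi <- compute_m_index(chron_of(c(1, 3, 5)))
  expect_equal(c(mi$m, mi$nc45, mi$nc12), c(0, 1 / 3, 1 / 3))
  mi <- compute_m_index(chron_of(c(4, 4, 2, 3)))
  expect_equal(c(mi$m, mi$nc45, mi$nc12), c(0.25, 0.5, 0.25))
})

test_that("years without contributing regions are missing, not zero", {
  chron <- tibble::tibble(region = "R1", year = 2000L,
                          modal_class = 3L, n_series = 1L)
  mi <- compute_m_index(chron, years = 2000:2001)
  expect_equal(mi$m, c(0, NA_real_))
  expect_equal(mi$n_regions, c(1L, 0L))
  mi2 <- compute_m_index(chron, years = 2000, min_regions = 2)
  expect_true(is.na(mi2$m))
})

test_that("pipeline index agrees with a brute-force oracle on random fixtures", {
  set.seed(101)
  for (i in 1:200) {
    rec <- random_records(n_regions = sample(2:6, 1), n_series = sample(1:4, 1),
                          years = 2000:2004, p_obs = 0.7)
    if (nrow(rec) == 0) next
    mi <- compute_m_index(aggregate_modal(rec), years = 2000:2004)
    expect_identical(mi$m, unname(oracle_m_index(rec, 2000:2004)))
    expect_identical(mi$m, mi$nc45 - mi$nc12)
  }
})

test_that("record order never changes the index", {
  set.seed(55)
  rec <- random_records(5, 3, 1990:1999)
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(compute_m_index(aggregate_modal(rec)),
               compute_m_index(aggregate_modal(shuffled)))
})

test_that("duplicating a series can move the regional mode only toward it", {
  set.seed(77)
  for (i in 1:50) {
    rec <- random_records(1, sample(2:5, 1), 2000:2002, p_obs = 0.9)
    if (nrow(rec) == 0) next
    dup_id <- sample(unique(rec$series_id), 1)
    dup <- rec[rec$series_id == dup_id, ]
    dup$series_id <- "DUPLICATE"
    before <- aggregate_modal(rec)
    after <- aggregate_modal(dplyr::bind_rows(rec, dup))
    joined <- dplyr::inner_join(before, after, by = c("region", "year"),
                                suffix = c("_a", "_b"))
    for (j in seq_len(nrow(joined))) {
      dup_cls <- dup$ord_class[dup$year == joined$year[j]]
      if (length(dup_cls) == 0) {
        expect_identical(joined$modal_class_b[j], joined$modal_class_a[j])
      } else if (joined$modal_class_b[j] != joined$modal_class_a[j]) {
        expect_true(joined$modal_class_b[j] %in% dup_cls)
      }
    }
  }
})

test_that("unit rescaling follows the compression formula and inverts", {
  expect_equal(rescale_unit(-1, n = 100), 0.005, ignore_attr = TRUE)
  n <- 64
  expect_equal(as.numeric(rescale_unit(0, n = n)), (0.5 * (n - 1) + 0.5) / n)
  m <- seq(-1, 1, by = 0.25)
  y <- rescale_unit(m)
  expect_true(all(y > 0 & y < 1))
  expect_equal(unscale_unit(y), m, tolerance = 1e-12)
  expect_error(rescale_unit(1.5), "must lie in")
})
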