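test_that("query construction validates selectors and time ordering", {
  expect_error(qr_query("image"), "allow_all")
  expect_s3_class(qr_query("image", allow_all = TRUE), "qr_query")
  expect_error(qr_query("study", patient_ids = "P", time_from = "20200101",
                        time_to = "20190101"), "time_from")
  expect_error(qr_query("study", patient_ids = "P", time_from = "21-3-4"),
               "malformed date")
  q <- qr_query("study", patient_ids = "P", time_from = as.Date("2019-02-03"))
  expect_identical(q$time_from, "20190203")
})

test_that("find filters match a brute-force scan of the fixture index", {
  co <- fixture_tree()$cohort
  prov <- fixture_provider()
  # modality filter at series level, every patient, every modality
  for (p in unique(co$series$patient_id)) {
    for (m in c("CT", "MR", "US")) {
      got <- qr_find(prov, qr_query("series", patient_ids = p, modalities = m))
      expect_identical(nrow(got),
                       sum(co$series$patient_id == p & co$series$modality == m))
    }
  }
  # time filter is half-open [from, to) on StudyDate
  d <- sort(unique(co$studies$study_date))
  mid <- d[ceiling(length(d) / 2)]
  got <- qr_find(prov, qr_query("study", time_from = mid, time_to = mid,
                                allow_all = TRUE))
  expect_identical(nrow(got), 0L)
  got <- qr_find(prov, qr_query("study", time_from = d[1], time_to = mid))
  expect_identical(nrow(got),
                   sum(co$studies$study_date >= d[1] & co$studies$study_date < mid))
  # accession number selector
  acc <- co$studies$accession_number[3]
  got <- qr_find(prov, qr_query("image", accession_numbers = acc))
  expect_identical(nrow(got), sum(co$images$study_uid ==
                                    co$studies$study_uid[3]))
})

test_that("find responses never leak attributes outside the restricted whitelist", {
  prov <- fixture_provider()
  for (level in c("patient", "study", "series", "image")) {
    got <- qr_find(prov, qr_query(level, allow_all = TRUE))
    expect_true(all(names(got) %in% basic_header_keys()),
                info = paste("level", level))
  }
  # underlying files do carry extended attributes
  rec <- prov$retrieve(fixture_tree()$cohort$images$sop_uid[1])$records[[1]]
  expect_true("Manufacturer" %in% names(rec$attrs))
  expect_false("Manufacturer" %in% basic_header_keys())
})

test_that("narrowing a query never adds results (monotonicity)", {
  co <- fixture_tree()$cohort
  prov <- fixture_provider()
  set.seed(11)
  dates <- sort(unique(co$studies$study_date))
  for (i in 1:20) {
    p <- sample(unique(co$images$patient_id), 1)
    base <- qr_find(prov, qr_query("image", patient_ids = p))
    narrowed_mod <- qr_find(prov, qr_query("image", patient_ids = p,
                                           modalities = sample(c("CT", "CR", "MR", "US"), 1)))
    expect_lte(nrow(narrowed_mod), nrow(base))
    expect_true(all(narrowed_mod$SOPInstanceUID %in% base$SOPInstanceUID))
    w <- sort(sample(dates, 2))
    narrowed_time <- qr_find(prov, qr_query("image", patient_ids = p,
                                            time_from = w[1], time_to = w[2]))
    expect_true(all(narrowed_time$SOPInstanceUID %in% base$SOPInstanceUID))
  }
})

test_that("retrieving everything found at image level yields exactly the found set", {
  prov <- fixture_provider()
  found <- qr_find(prov, qr_query("image", allow_all = TRUE))
  got <- qr_retrieve(prov, found$SOPInstanceUID)
  expect_setequal(vapply(got, `[[`, character(1), "sop_uid"),
                  found$SOPInstanceUID)
  expect_length(attr(got, "not_found"), 0L)
})

test_that("retrieve expands series/study identifiers and reports unknowns", {
  co <- fixture_tree()$cohort
  prov <- fixture_provider()
  s <- co$series$series_uid[which.max(tabulate(match(co$images$series_uid,
                                                     co$series$series_uid)))]
  n <- sum(co$images$series_uid == s)
  got <- qr_retrieve(prov, s)
  expect_length(got, n)
  # full data sets carry at least one attribute absent from basic headers
  expect_true(all(vapply(got, function(r)
    any(!names(r$attrs) %in% basic_header_keys()), logical(1))))
  expect_length(qr_retrieve(prov, character()), 0L)
  mixed <- qr_retrieve(prov, c("no.such.uid", co$images$sop_uid[1]))
  expect_identical(attr(mixed, "not_found"), "no.such.uid")
  expect_length(mixed, 1L)
})

test_that("a configured throttle spreads retrievals over rate windows", {
  prov <- fixture_provider()
  co <- fixture_tree()$cohort
  clk <- sim_clock(0)
  got <- qr_retrieve(prov, co$images$sop_uid[1:5],
                     throttle = throttle_config(2), clock = clk)
  ts <- attr(got, "timestamps")
  expect_length(ts, 5L)
  # 5 items at 2/minute need at least 3 windows: starts at 0, 60, 120
  expect_gte(max(ts) - min(ts), 120)
  windows <- table(floor(ts / 60))
  expect_true(all(windows <= 2))
  # without a throttle, simulated time does not advance
  clk2 <- sim_clock(0)
  got2 <- qr_retrieve(prov, co$images$sop_uid[1:5], clock = clk2)
  expect_identical(max(attr(got2, "timestamps")), 0)
})

test_that("image selection follows InstanceNumber order with the stated conventions", {
  imgs <- data.table::data.table(
    SOPInstanceUID = c("u3", "u1", "u2"), InstanceNumber = c(3L, 1L, 2L))
  expect_identical(select_images(imgs, "first")$InstanceNumber, 1L)
  expect_identical(select_images(imgs, "all")$InstanceNumber, 1:3)
  four <- data.table::data.table(SOPInstanceUID = paste0("u", 1:4),
                                 InstanceNumber = 1:4)
  expect_identical(select_images(four, "middle")$InstanceNumber, 2L)  # ceil(4/2)
  five <- data.table::data.table(SOPInstanceUID = paste0("u", 1:5),
                                 InstanceNumber = 1:5)
  expect_identical(select_images(five, "middle")$InstanceNumber, 3L)
  expect_error(select_images(imgs[0, ], "first"), "empty")
  # missing InstanceNumber: lexical SOP order, flagged
  noin <- data.table::data.table(SOPInstanceUID = c("b", "a"),
                                 InstanceNumber = c(NA_integer_, NA_integer_))
  sel <- select_images(noin, "first")
  expect_identical(sel$SOPInstanceUID, "a")
  expect_true(attr(sel, "instance_number_fallback"))
})

test_that("first-image selection over all series covers each series exactly once", {
  co <- fixture_tree()$cohort
  prov <- fixture_provider()
  found <- qr_find(prov, qr_query("image", allow_all = TRUE))
  sel <- data.table::rbindlist(lapply(split(found, by = "SeriesInstanceUID"),
                                      select_images, method = "first"))
  expect_identical(nrow(sel), length(unique(co$images$series_uid)))
  expect_false(anyDuplicated(sel$SeriesInstanceUID) > 0)
})
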