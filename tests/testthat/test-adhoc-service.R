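new_service <- function(clock = sim_clock(1000), profile = deid_profile()) {
  adhoc_service(fixture_provider(), new_store(), fixture_connector(),
                profile = profile,
                report_acc = tree_report_accessions(fixture_tree()),
                clock = clock)
}

# a fixture patient with imaging, its pseudonym and index slices
imaged_patient <- function() {
  co <- fixture_tree()$cohort
  counts <- per_patient_counts(co)
  pid <- counts$patient_id[counts$detected][which.max(counts$n_series[counts$detected])]
  list(pid = pid,
       psn = fixture_connector()$pseudonymize("patient", pid),
       studies = co$studies[co$studies$patient_id == pid, ],
       series = co$series[co$series$patient_id == pid, ],
       images = co$images[co$images$patient_id == pid, ])
}

test_that("session keys authorize exactly the session's patients until expiry", {
  clk <- sim_clock(0)
  svc <- new_service(clock = clk)
  psn <- fixture_pseudonyms()
  expect_error(create_session(svc, "alice", character()), "non-empty")
  s <- create_session(svc, "alice", psn[1:3])
  expect_match(s$key, "^SES-")
  expect_true(authorize(svc, s$key, psn[1])$allow)
  d <- authorize(svc, s$key, psn[5])
  expect_false(d$allow)
  expect_identical(d$reason, "patient_not_in_session")
  al <- audit_log(svc)
  expect_identical(al$decision[nrow(al)], "deny")
  expect_false(authorize(svc, "SES-forged", psn[1])$allow)
  clk$sleep(8 * 3600 + 1)
  e <- authorize(svc, s$key, psn[1])
  expect_false(e$allow)
  expect_identical(e$reason, "session_expired")
})

test_that("the study/series listing mirrors the index with pseudonymous identifiers", {
  svc <- new_service()
  p <- imaged_patient()
  s <- create_session(svc, "bob", p$psn)
  li <- list_patient_imaging(svc, s$key, p$psn)
  expect_length(li, nrow(p$studies))
  expect_identical(sum(vapply(li, `[[`, integer(1), "n_series")),
                   nrow(p$series))
  dates <- vapply(li, `[[`, character(1), "study_date")
  expect_identical(dates, sort(dates))
  # identifiers are pseudonymized, no raw UID or PID appears
  flat <- paste(unlist(li), collapse = " ")
  expect_false(grepl(p$pid, flat, fixed = TRUE))
  expect_false(any(vapply(p$studies$study_uid, grepl, logical(1), x = flat,
                          fixed = TRUE)))
  # a patient with no imaging gets an empty listing, not an error
  co <- fixture_tree()$cohort
  no_img <- co$patients$patient_id[!co$patients$has_imaging][1]
  no_psn <- fixture_connector()$pseudonymize("patient", no_img)
  s2 <- create_session(svc, "bob", no_psn)
  expect_identical(list_patient_imaging(svc, s2$key, no_psn), list())
})

test_that("every service operation denies an out-of-session patient", {
  svc <- new_service()
  psn <- fixture_pseudonyms()
  s <- create_session(svc, "carol", psn[1])
  outsider <- psn[2]
  req <- adhoc_request(id_scope("patient", outsider))
  expect_false(authorize(svc, s$key, outsider)$allow)
  expect_error(list_patient_imaging(svc, s$key, outsider), "denied")
  expect_error(adhoc_metadata(svc, s$key, req), "denied")
  expect_error(export_images(svc, s$key, req, tempfile()), "denied")
  # identifier kinds that resolve to an outsider's images are denied too
  co <- fixture_tree()$cohort
  out_uid <- co$series$series_uid[co$series$patient_id ==
    fixture_connector()$resolve("patient", outsider)][1]
  out_psn_uid <- fixture_connector()$pseudonymize("instance_uid", out_uid)
  req2 <- adhoc_request(id_scope("instance_uid", out_psn_uid))
  expect_error(adhoc_metadata(svc, s$key, req2), "denied")
})

test_that("audit entries match service calls one-to-one, allow or deny", {
  svc <- new_service()
  psn <- fixture_pseudonyms()
  s <- create_session(svc, "dora", psn[1:2])               # 1
  invisible(authorize(svc, s$key, psn[1]))                 # 2
  try(list_patient_imaging(svc, s$key, psn[5]), silent = TRUE)  # 3 deny
  invisible(list_patient_imaging(svc, s$key, psn[1]))      # 4
  req <- adhoc_request(id_scope("patient", psn[1]), aggregation = "study")
  invisible(adhoc_metadata(svc, s$key, req))               # 5
  invisible(export_images(svc, s$key,
    adhoc_request(id_scope("patient", psn[1]), format = "jpeg",
                  selection = "first"), tempfile()))       # 6
  al <- audit_log(svc)
  expect_identical(nrow(al), 6L)
  expect_identical(sum(al$decision == "deny"), 1L)
  expect_identical(unique(al$username), "dora")
})

test_that("metadata aggregation levels and scopes match the fixture", {
  svc <- new_service()
  p <- imaged_patient()
  s <- create_session(svc, "erin", p$psn)
  by_study <- adhoc_metadata(svc, s$key,
    adhoc_request(id_scope("patient", p$psn), aggregation = "study"))
  expect_identical(nrow(by_study), nrow(p$studies))
  expect_identical(sum(by_study$n_images), nrow(p$images))
  by_series <- adhoc_metadata(svc, s$key,
    adhoc_request(id_scope("patient", p$psn), aggregation = "series"))
  expect_identical(nrow(by_series), nrow(p$series))
  by_image <- adhoc_metadata(svc, s$key,
    adhoc_request(id_scope("patient", p$psn), aggregation = "image"))
  expect_identical(nrow(by_image), nrow(p$images))
  # extended scope includes attributes absent from basic scope
  ext <- adhoc_metadata(svc, s$key,
    adhoc_request(id_scope("patient", p$psn), aggregation = "series",
                  scope = "extended"))
  expect_identical(nrow(ext), nrow(p$series))
  expect_true("Manufacturer" %in% names(ext))
  expect_false("Manufacturer" %in% names(by_series))
  expect_false("PatientName" %in% names(ext))   # de-identified
})

test_that("CSV and JSON renderings of a metadata result carry identical content", {
  svc <- new_service()
  p <- imaged_patient()
  s <- create_session(svc, "fred", p$psn)
  res <- adhoc_metadata(svc, s$key,
    adhoc_request(id_scope("patient", p$psn), aggregation = "series"))
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_adhoc_result(res, fc, "csv")
  write_adhoc_result(res, fj, "json")
  from_csv <- utils::read.csv(fc, colClasses = "character", na.strings = NULL)
  from_json <- jsonlite::fromJSON(readLines(fj))
  from_json[] <- lapply(from_json, function(x) {
    x <- as.character(x); x[is.na(x)] <- ""; x
  })
  expect_identical(dim(from_csv), dim(from_json))
  expect_identical(names(from_csv), names(from_json))
  for (cn in names(from_csv))
    expect_identical(from_csv[[cn]], from_json[[cn]], info = cn)
})

test_that("image export honors selection, formats and the ultrasound block", {
  svc <- new_service()
  co <- fixture_tree()$cohort
  # a non-US series with several images
  ser <- co$series[co$series$modality != "US", ]
  ser_n <- vapply(ser$series_uid, function(u) sum(co$images$series_uid == u),
                  integer(1))
  pick <- ser[which.max(ser_n), ]
  n_pick <- max(ser_n)
  psn <- fixture_connector()$pseudonymize("patient", pick$patient_id)
  ser_psn <- fixture_connector()$pseudonymize("instance_uid", pick$series_uid)
  s <- create_session(svc, "gina", psn)

  d1 <- file.path(tempdir(), "exp-all"); unlink(d1, recursive = TRUE)
  ex <- export_images(svc, s$key,
    adhoc_request(id_scope("instance_uid", ser_psn), format = "jpeg",
                  selection = "all"), d1)
  expect_identical(sum(ex$manifest$status == "exported"), n_pick)
  expect_identical(length(list.files(d1, pattern = "\\.jpg$")), n_pick)
  expect_false(ex$empty_export)
  # manifest links to warehouse group ids derived from pseudonymous UIDs
  expect_true(all(grepl("^[0-9a-f]{16}$",
                        ex$manifest$group_id[ex$manifest$status == "exported"])))

  d2 <- file.path(tempdir(), "exp-first"); unlink(d2, recursive = TRUE)
  ex2 <- export_images(svc, s$key,
    adhoc_request(id_scope("instance_uid", ser_psn), format = "dicom",
                  selection = "first"), d2)
  expect_identical(sum(ex2$manifest$status == "exported"), 1L)
  dcm <- list.files(d2, pattern = "\\.dcm$", full.names = TRUE)
  expect_length(dcm, 1L)
  # the exported DICOM passes the de-identification audit
  back <- dcm_read(dcm)
  expect_false(any(c("PatientName", "PatientBirthDate", "OtherPatientIDs")
                   %in% names(back$attrs)))
  expect_match(back$attrs$PatientID, "^PSN-")
  expect_match(back$attrs$SOPInstanceUID, "^2\\.25\\.")

  # an ultrasound series is denied: zero files, deny in manifest and audit
  us <- co$series[co$series$modality == "US", ][1, ]
  us_owner <- fixture_connector()$pseudonymize("patient", us$patient_id)
  us_psn <- fixture_connector()$pseudonymize("instance_uid", us$series_uid)
  s2 <- create_session(svc, "gina", us_owner)
  d3 <- file.path(tempdir(), "exp-us"); unlink(d3, recursive = TRUE)
  ex3 <- export_images(svc, s2$key,
    adhoc_request(id_scope("instance_uid", us_psn), format = "jpeg"), d3)
  expect_identical(sum(ex3$manifest$status == "exported"), 0L)
  expect_identical(ex3$manifest$reason[1], "modality_blocklisted")
  expect_true(ex3$empty_export)
  expect_identical(length(list.files(d3, pattern = "\\.jpg$")), 0L)
  al <- audit_log(svc)
  expect_match(al$params[nrow(al)], "denied_series")
})
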