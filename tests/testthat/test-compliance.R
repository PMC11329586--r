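# The audit engine: reference inference, tolerance logic, horizontal and
# vertical audits, stratification. Derived expectations are computed with
# independent brute-force oracles inside the tests.

test_that("infer_reference takes the modal value with deterministic ties", {
  mk <- function(trs) lapply(seq_along(trs), function(i)
    make_run(sprintf("s%02d", i), values = list(RepetitionTime = trs[i]),
             run_id = paste0("r", i)))
  ref <- infer_reference(make_hier(mk(c(2300, 2300, 2000)))$runs,
                         names = "RepetitionTime")
  expect_equal(ref$entries$RepetitionTime$value, 2300)
  expect_identical(unname(ref$support[["RepetitionTime"]]), 2L)

  ref <- infer_reference(mk(c(2.9, 3.0, 2.9, 3.0)), names = "RepetitionTime")
  expect_equal(ref$entries$RepetitionTime$value, 2.9)  # tie -> smallest

  # absent everywhere -> omitted and listed un-inferable
  ref <- infer_reference(mk(c(1, 1)), names = c("RepetitionTime", "EchoTime"))
  expect_null(ref$entries$EchoTime)
  expect_identical(attr(ref, "uninferable"), "EchoTime")
})

test_that("inferred value equals brute-force frequency argmax (property)", {
  set.seed(41)
  for (rep in 1:30) {
    vals <- sample(c(2000, 2300, 2500, 3000), 50, replace = TRUE)
    runs <- lapply(seq_along(vals), function(i)
      make_run(sprintf("s%02d", i), values = list(RepetitionTime = vals[i]),
               run_id = paste0("r", i)))
    ref <- infer_reference(runs, names = "RepetitionTime")
    tab <- table(vals)
    oracle <- min(as.numeric(names(tab)[tab == max(tab)]))
    expect_equal(ref$entries$RepetitionTime$value, oracle)
    # order independence
    ref2 <- infer_reference(runs[sample(length(runs))], names = "RepetitionTime")
    expect_equal(ref2$entries$RepetitionTime$value, oracle)
  }
})

test_that("acceptable_range implements R +/- t*R with inclusive bounds", {
  expect_equal(acceptable_range(3, 0.05), c(2.85, 3.15))
  expect_equal(round(acceptable_range(6.66, 0.05), 2), c(6.33, 6.99))
  expect_equal(acceptable_range(1234, 0), c(1234, 1234))
  expect_error(acceptable_range(3, -0.01), "non-negative")
})

test_that("value_compliant honours kind and tolerance semantics", {
  te_obs <- param_value("EchoTime", 2.9)
  te_ref <- param_value("EchoTime", 3.0)
  expect_false(value_compliant(te_obs, te_ref, 0))
  expect_true(value_compliant(te_obs, te_ref, 0.05))   # 2.9 in [2.85, 3.15]
  # boundary is inclusive
  expect_true(value_compliant(param_value("EchoTime", 2.85), te_ref, 0.05))

  ped_a <- param_value("PhaseEncodingDirection", "AP")
  ped_p <- param_value("PhaseEncodingDirection", "PA")
  for (t in c(0, 0.05, 1)) expect_false(value_compliant(ped_a, ped_p, t))
  expect_true(value_compliant(ped_a, param_value("PhaseEncodingDirection", "AP"), 0))

  expect_error(value_compliant(te_obs, ped_a, 0), "kind mismatch")

  ang <- function(v) param_value("Angulation", v)
  expect_true(value_compliant(ang(c(1, 0, 0, 0, 1, 0)), ang(c(1, 0, 0, 0, 1, 0)), 0.5))
  expect_false(value_compliant(ang(c(1, 0, 0, 0, 1, 0)), ang(c(0, 1, 0, 1, 0, 0)), 0.5))
})

test_that("check_run emits one deviation per failing or absent parameter", {
  ref <- infer_reference(list(make_run("s1")), names(base_values()))
  expect_identical(nrow(check_run(make_run("s2"), ref)), 0L)

  v <- base_values(); v$EchoTime <- 3.5; v$PhaseEncodingDirection <- "PA"
  d <- check_run(make_run("s3", values = v), ref)
  expect_identical(nrow(d), 2L)
  expect_setequal(d$parameter, c("EchoTime", "PhaseEncodingDirection"))
  expect_true(all(d$type == "mismatch"))

  d <- check_run(make_run("s4", absent = "PhaseEncodingDirection"), ref)
  expect_identical(nrow(d), 1L)
  expect_identical(d$type, "missing")
  expect_true(is.na(d$observed))
})

test_that("percentages follow the count formula and truncation display", {
  p <- noncompliance_percent(980, 1521)
  expect_identical(format_pct(p$noncompliant_pct), "64.43")
  expect_identical(format_pct(100 * 541 / 1521), "35.56")  # truncation, not rounding
  p <- noncompliance_percent(14, 5873)
  expect_identical(format_pct(p$compliant_pct), "99.76")
  p <- noncompliance_percent(0, 7)
  expect_identical(format_pct(p$noncompliant_pct), "0.00")
  expect_identical(format_pct(p$compliant_pct), "100.00")
  expect_error(noncompliance_percent(1, 0), "undefined")
  expect_error(noncompliance_percent(5, 3), "<=")

  # Eq. 1 conservation at full precision, for arbitrary count pairs
  set.seed(51)
  for (i in 1:50) {
    n <- sample(1:5000, 1); k <- sample(0:n, 1)
    p <- noncompliance_percent(k, n)
    expect_identical(p$noncompliant_pct + p$compliant_pct, 100)
  }
})

test_that("horizontal audit aggregates runs to subjects per the single-run rule", {
  h <- cohort_hier(3, deviants = "sub-002")
  s <- horizontal_audit(h, "ANAT_T1W")[[1]]
  expect_identical(s$n_noncompliant, 1L)
  expect_identical(format_pct(s$noncompliant_pct), "33.33")
  expect_identical(unname(s$subject_status["sub-002"]), "non-compliant")
  expect_identical(s$deviant_parameters, "EchoTime")

  s <- horizontal_audit(cohort_hier(5), "ANAT_T1W")[[1]]
  expect_identical(s$n_noncompliant, 0L)
  expect_identical(format_pct(s$compliant_pct), "100.00")

  # flipping any single run of a compliant subject flips the subject
  h2 <- make_hier(list(make_run("sub-001", session = "ses-01"),
                       make_run("sub-001", session = "ses-02"),
                       make_run("sub-002", session = "ses-01"),
                       make_run("sub-002", session = "ses-02")))
  v <- base_values(); v$FlipAngle <- 12
  h3 <- make_hier(list(make_run("sub-001", session = "ses-01"),
                       make_run("sub-001", session = "ses-02", values = v),
                       make_run("sub-002", session = "ses-01"),
                       make_run("sub-002", session = "ses-02")))
  ref <- infer_reference(runs_for(h2, "ANAT_T1W"))
  s2 <- horizontal_audit(h2, "ANAT_T1W", ref = ref)[[1]]
  s3 <- horizontal_audit(h3, "ANAT_T1W", ref = ref)[[1]]
  expect_identical(unname(s2$subject_status["sub-001"]), "compliant")
  expect_identical(unname(s3$subject_status["sub-001"]), "non-compliant")
})

test_that("vendor stratification matches brute-force per-vendor recount", {
  set.seed(61)
  vendors <- sample(c("SIEMENS", "GE", "PHILIPS"), 18, replace = TRUE)
  runs <- lapply(1:18, function(i) {
    v <- base_values()
    if (i %% 5 == 0) v$EchoTime <- 3.4
    make_run(sprintf("sub-%03d", i), values = v, vendor = vendors[i],
             run_id = paste0("r", i))
  })
  h <- make_hier(runs)
  ss <- horizontal_audit(h, "ANAT_T1W", strata_keys = "vendor")
  expect_length(ss, length(unique(vendors)))
  for (s in ss) {
    vend <- sub("vendor=", "", s$stratum)
    sub_runs <- Filter(function(r) r$vendor == vend, runs)
    ref <- infer_reference(sub_runs)
    nc <- sum(vapply(sub_runs, function(r) nrow(check_run(r, ref)) > 0, TRUE))
    expect_identical(s$n_noncompliant, as.integer(nc))
    expect_identical(s$n_total, length(sub_runs))
  }
})

test_that("stratify partitions disjointly and exhaustively", {
  v_ap <- base_values(); v_pa <- base_values(); v_pa$PhaseEncodingDirection <- "PA"
  runs <- c(lapply(1:3, function(i) make_run(paste0("a", i), values = v_ap,
                                             run_id = paste0("ap", i))),
            lapply(1:2, function(i) make_run(paste0("b", i), values = v_pa,
                                             run_id = paste0("pa", i))))
  st <- stratify(runs, "ped")
  expect_length(st, 2L)
  expect_setequal(names(st), c("ped=AP", "ped=PA"))

  expect_length(stratify(runs, "vendor"), 1L)
  expect_error(stratify(runs, "planet"), "unknown strata keys")

  # runs lacking the key field land in an unannotated stratum
  runs2 <- c(runs, list(make_run("c1", absent = "PhaseEncodingDirection",
                                 run_id = "na1")))
  st2 <- stratify(runs2, "ped")
  expect_true("ped=unannotated" %in% names(st2))

  set.seed(71)
  for (rep in 1:10) {
    rr <- lapply(1:15, function(i)
      make_run(sprintf("s%02d", i), vendor = sample(c("GE", "PHILIPS", ""), 1),
               run_id = paste0("r", i)))
    st <- stratify(rr, c("vendor", "ped"))
    ids <- unlist(lapply(st, function(g) vapply(g, `[[`, "", "run_id")))
    expect_identical(sort(unname(ids)), sort(paste0("r", 1:15)))  # exhaustive, disjoint
  }
})

test_that("vertical audit checks fieldmap geometry and shim consistency", {
  geom <- list(FieldOfView = 216, NumberOfSlices = 60, SliceThickness = 2.4,
               Angulation = c(1, 0, 0, 0, 1, 0))
  mk <- function(mod, over = list(), shim = "tune_up") {
    v <- c(base_values(), geom)
    v$ShimMode <- shim
    for (nm in names(over)) v[[nm]] <- over[[nm]]
    make_run("sub-001", mod, v, run_id = mod)
  }
  h_ok <- make_hier(list(mk("FMAP_DIR_AP_EPI"), mk("FUNC_TASK_REST_BOLD")))
  expect_identical(nrow(suppressMessages(vertical_audit(h_ok, "sub-001"))), 0L)

  h_bad <- make_hier(list(mk("FMAP_DIR_AP_EPI", list(NumberOfSlices = 64)),
                          mk("FUNC_TASK_REST_BOLD")))
  d <- vertical_audit(h_bad, "sub-001")
  expect_identical(nrow(d), 1L)
  expect_identical(d$parameter, "NumberOfSlices")
  expect_identical(d$rule, "fieldmap-geometry")

  h_shim <- make_hier(list(mk("FMAP_DIR_AP_EPI"), mk("FUNC_TASK_REST_BOLD"),
                           mk("ANAT_T1W", shim = "advanced")))
  d <- vertical_audit(h_shim, "sub-001")
  expect_true("shim-consistency" %in% d$rule)
  expect_identical(d$value_a[d$rule == "shim-consistency"], "advanced")

  # no fieldmap/EPI pair: empty geometry result, message logged
  h_none <- make_hier(list(mk("ANAT_T1W")))
  expect_message(d0 <- vertical_audit(h_none, "sub-001"), "no fieldmap")
  expect_identical(nrow(d0), 0L)
  expect_error(vertical_audit(h_ok, "sub-zzz"), "not present")
})

test_that("tolerance sweep is monotone; categorical deviations ignore t", {
  # numeric-only deviations within 5 percent of the reference
  v <- base_values(); v$EchoTime <- 3 * 1.04
  h_num <- make_hier(c(lapply(1:6, function(i)
    make_run(sprintf("s%02d", i), run_id = paste0("r", i))),
    list(make_run("s99", values = v, run_id = "r99"))))
  sw <- tolerance_sweep(h_num, "ANAT_T1W")
  expect_true(all(diff(sw) <= 1e-12))
  expect_gt(sw[["0"]], 0)
  expect_equal(sw[["0.05"]], 0)

  # categorical-only deviations: flat curve
  v2 <- base_values(); v2$PhaseEncodingDirection <- "PA"
  h_cat <- make_hier(c(lapply(1:6, function(i)
    make_run(sprintf("s%02d", i), run_id = paste0("r", i))),
    list(make_run("s99", values = v2, run_id = "r99"))))
  sw2 <- tolerance_sweep(h_cat, "ANAT_T1W")
  expect_true(all(sw2 == sw2[[1]]))
  expect_gt(sw2[[1]], 0)

  # mixed fixture: equals an independent per-t recount over subjects
  v3 <- base_values(); v3$EchoTime <- 3 * 1.3
  h_mix <- make_hier(c(lapply(1:5, function(i)
    make_run(sprintf("s%02d", i), run_id = paste0("r", i))),
    list(make_run("s98", values = v2, run_id = "r98"),
         make_run("s99", values = v3, run_id = "r99"))))
  ref <- infer_reference(runs_for(h_mix, "ANAT_T1W"))
  sw3 <- tolerance_sweep(h_mix, "ANAT_T1W", ref = ref)
  for (t in names(sw3)) {
    rs <- runs_for(h_mix, "ANAT_T1W")
    bad <- vapply(rs, function(r) {
      any(vapply(names(ref$entries), function(nm) {
        p <- r$parameters[[nm]]
        is.null(p) || !p$present ||
          !value_compliant(p, ref$entries[[nm]], as.numeric(t))
      }, TRUE))
    }, TRUE)
    expect_equal(sw3[[t]],
                 100 * length(unique(vapply(rs[bad], `[[`, "", "subject_id"))) /
                   length(unique(vapply(rs, `[[`, "", "subject_id"))))
  }
  expect_error(tolerance_sweep(h_mix, "ANAT_T1W", t_values = c(0.05, 0)),
               "ascending")
})

test_that("multi-echo runs audit within their own echo stratum", {
  v2 <- base_values(); v2$EchoTime <- 12
  runs <- c(lapply(1:3, function(i)
    make_run(sprintf("s%02d", i), echo = 1L, run_id = paste0("e1r", i))),
    lapply(1:3, function(i)
      make_run(sprintf("s%02d", i), values = v2, echo = 2L,
               run_id = paste0("e2r", i))))
  ss <- horizontal_audit(make_hier(runs), "ANAT_T1W")
  expect_length(ss, 2L)  # echo stratum added automatically
  expect_true(all(vapply(ss, `[[`, 0L, "n_noncompliant") == 0L))
})
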