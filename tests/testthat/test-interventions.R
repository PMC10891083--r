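get_class <- function(circ, pre, post) {
  Filter(function(x) x$pre == pre && x$post == post, circ$classes)[[1]]
}

test_that("depression scales SST pathways by 0.6 and nothing else", {
  circ <- build_circuit(circuit_config(duration = 100), seed = 1)
  w_sst <- get_class(circ, "SST", "Pyr")$g_syn
  w_pv <- get_class(circ, "PV", "Pyr")$g_syn
  dep <- apply_depression(circ)
  expect_equal(get_class(dep, "SST", "Pyr")$g_syn, 0.6 * w_sst)
  expect_equal(get_class(dep, "SST", "PV")$g_syn,
               0.6 * get_class(circ, "SST", "PV")$g_syn)
  expect_equal(get_class(dep, "PV", "Pyr")$g_syn, w_pv)
  # Pyr apical tonic x0.6, somatic untouched
  expect_equal(dep$tonic_scale$Pyr, c(1, 0.6))
  # interneuron tonic reduced by 40% of the SST-contribution fraction
  fr <- circ$config$sst_tonic_frac
  expect_equal(dep$tonic_scale$SST, 1 - 0.4 * fr)
  # worked example: fraction 0.5 gives x0.8
  circ5 <- build_circuit(circuit_config(duration = 100,
                                        sst_tonic_frac = 0.5), seed = 1)
  expect_equal(apply_depression(circ5)$tonic_scale$PV, 0.8)
  expect_error(apply_depression(dep), "already applied")
  expect_equal(dep$condition, "mdd")
})

test_that("alpha5-PAM boosts only apical tonic and SST->Pyr, linearly in dose", {
  circ <- build_circuit(circuit_config(duration = 100), seed = 1)
  w_sst <- get_class(circ, "SST", "Pyr")$g_syn
  # dose 0 is the identity
  id <- apply_a5pam(circ, dose = 0)
  expect_equal(get_class(id, "SST", "Pyr")$g_syn, w_sst)
  expect_equal(id$tonic_scale$Pyr, c(1, 1))
  # reference dose: x1.6
  ref <- apply_a5pam(circ, dose = 1)
  expect_equal(get_class(ref, "SST", "Pyr")$g_syn, 1.6 * w_sst)
  expect_equal(ref$tonic_scale$Pyr[2], 1.6)
  expect_equal(ref$tonic_scale$Pyr[1], 1)
  expect_equal(ref$tonic_scale$SST, 1)
  expect_equal(get_class(ref, "PV", "Pyr")$g_syn,
               get_class(circ, "PV", "Pyr")$g_syn)
  # half dose: x1.3
  half <- apply_a5pam(circ, dose = 0.5)
  expect_equal(get_class(half, "SST", "Pyr")$g_syn, 1.3 * w_sst)
  expect_error(apply_a5pam(circ, dose = -0.1), "non-negative")
  expect_error(apply_a5pam(ref, dose = 1), "already")
})

test_that("dose scaling is monotone across the sweep range", {
  circ <- build_circuit(circuit_config(duration = 100), seed = 1)
  doses <- c(0.25, 0.5, 0.75, 1, 1.25, 1.5)
  w <- sapply(doses, function(d)
    get_class(apply_a5pam(circ, dose = d), "SST", "Pyr")$g_syn)
  tonic <- sapply(doses, function(d)
    apply_a5pam(circ, dose = d)$tonic_scale$Pyr[2])
  expect_true(all(diff(w) > 0))
  expect_true(all(diff(tonic) > 0))
})

test_that("non-selective PAM boosts every inhibitory and tonic conductance", {
  circ <- build_circuit(circuit_config(duration = 100), seed = 1)
  ns <- apply_nonselective_pam(circ)
  expect_equal(get_class(ns, "PV", "Pyr")$g_syn,
               1.6 * get_class(circ, "PV", "Pyr")$g_syn)
  expect_equal(get_class(ns, "VIP", "SST")$g_syn,
               1.6 * get_class(circ, "VIP", "SST")$g_syn)
  # excitatory untouched
  expect_equal(get_class(ns, "Pyr", "SST")$g_syn,
               get_class(circ, "Pyr", "SST")$g_syn)
  expect_equal(ns$tonic_scale$SST, 1.6)
  expect_equal(ns$tonic_scale$Pyr, c(1.6, 1.6))
  expect_error(apply_nonselective_pam(ns), "already")
})

test_that("depression bookkeeping: inhibitory conductance drops by 0.4 x SST share", {
  circ <- build_circuit(circuit_config(duration = 100), seed = 1)
  tot <- total_inhibitory_conductance(circ)
  sst <- sum(sapply(Filter(function(x) x$pre == "SST" &&
                             x$E_syn < -60, circ$classes),
                    function(x) x$g_syn * length(x$pre_edges)))
  dep <- apply_depression(circ)
  expect_equal(total_inhibitory_conductance(dep),
               tot - 0.4 * sst, tolerance = 1e-12)
})

test_that("condition labels parse into the right transform chains", {
  circ <- build_circuit(circuit_config(duration = 100), seed = 1)
  expect_equal(apply_condition(circ, "healthy")$condition, "healthy")
  expect_equal(apply_condition(circ, "mdd")$condition, "mdd")
  c1 <- apply_condition(circ, "mdd+a5pam:50%")
  expect_equal(c1$condition, "mdd+a5pam:50%")
  expect_equal(c1$tonic_scale$Pyr[2], 0.6 * 1.3)
  c2 <- apply_condition(circ, "mdd+nspam")
  expect_equal(c2$tonic_scale$Pyr[2], 0.6 * 1.6)
  expect_error(apply_condition(circ, "bogus"), "unknown condition")
})
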