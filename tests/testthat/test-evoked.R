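arr <- tiny_array()

test_that("epoch bookkeeping: kept + rejected = events with full windows", {
  rec <- generate_evoked_recording(fast_sim(duration = 30), arr)
  ep <- make_epochs(rec)
  full <- sum(rec$events$time + (-0.070) >= 0 &
                rec$events$time + 0.5 <= rec_duration(rec))
  expect_equal(ep$n_kept + ep$n_rejected, full)
  expect_equal(ep$n_rejected, 0)

  # a mask over exactly one event's window drops exactly that epoch
  tvictim <- rec$events$time[10]
  m <- artifact_mask(cbind(tvictim + 0.1, tvictim + 0.2), rec_duration(rec))
  ep2 <- make_epochs(rec, m)
  expect_equal(ep2$n_kept, ep$n_kept - 1)
  expect_equal(ep2$n_rejected, 1)
  expect_false(tvictim %in% ep2$event_times)

  # mask covering everything leaves no epochs and warns
  mall <- artifact_mask(cbind(0, rec_duration(rec)), rec_duration(rec))
  expect_warning(ep3 <- make_epochs(rec, mall), "no epochs")
  expect_equal(ep3$n_kept, 0)
})

test_that("baseline correction zeroes the prestimulus mean", {
  rec <- generate_evoked_recording(fast_sim(duration = 20), arr)
  ep <- baseline_correct(make_epochs(rec))
  b <- ep$times >= -0.070 & ep$times < 0
  bl <- apply(ep$epochs[, , b, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-12 * max(abs(ep$epochs)))

  # constant epochs become all-zero; zero-baseline epochs are unchanged
  ep$epochs[] <- 3
  expect_lt(max(abs(baseline_correct(ep)$epochs)), 1e-12)
})

test_that("averaging and group averaging behave as arithmetic means", {
  rec <- generate_evoked_recording(silent_sim(duration = 20), arr)
  ep <- baseline_correct(make_epochs(rec))
  ev <- average_epochs(ep)
  # identical epochs average to the epoch
  ep2 <- ep
  for (e in seq_len(dim(ep2$epochs)[1])) ep2$epochs[e, , ] <- ep$epochs[1, , ]
  expect_equal(average_epochs(ep2)$mean, ep$epochs[1, , ], tolerance = 1e-12)
  # +x / -x pairs cancel
  ep3 <- ep
  ep3$epochs <- ep$epochs[1:2, , , drop = FALSE]
  ep3$epochs[2, , ] <- -ep3$epochs[1, , ]
  ep3$n_kept <- 2L
  expect_lt(max(abs(average_epochs(ep3)$mean)), 1e-20)

  # group average is permutation invariant and matches channels across caps
  evs <- lapply(1:3, function(s) {
    a <- tiny_array(seed = s)
    r <- generate_evoked_recording(silent_sim(duration = 20, seed = s), a)
    average_epochs(baseline_correct(make_epochs(r)))
  })
  g1 <- group_average(evs)
  g2 <- group_average(rev(evs), template = evs[[1]]$channels)
  expect_equal(g1$mean, g2$mean, tolerance = 1e-12)
})

test_that("template matching is an optimal bijection (brute-force check)", {
  # small synthetic assignment problems: Hungarian equals exhaustive search
  set.seed(42)
  for (rep in 1:5) {
    n <- 5
    cost <- matrix(runif(n * n), n)
    got <- opmpipe:::solve_assignment(cost)
    perms <- gtools_permutations <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in gtools_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    best <- min(vapply(perms(1:n), function(p)
      sum(cost[cbind(1:n, p)]), numeric(1)))
    expect_equal(sum(cost[cbind(1:n, got)]), best, tolerance = 1e-12)
  }
  # matching a shuffled copy of an array recovers the permutation
  a <- tiny_array(seed = 3)
  perm <- sample(nrow(a))
  idx <- match_channels_to_template(a, a[perm, ])
  expect_equal(a[perm, ]$channel_id[idx], a$channel_id)
})

test_that("tangential norm: Pythagoras, rotation invariance, positivity", {
  rec <- generate_evoked_recording(fast_sim(duration = 20), arr)
  ev <- average_epochs(baseline_correct(make_epochs(rec)))
  tn <- tangential_norm(ev)
  expect_true(all(tn$mean >= 0))
  expect_equal(nrow(tn$mean), sum(ev$channels$axis == "tangential_2"))

  # hand case: t1 = 3, t2 = 4 -> 5
  ev35 <- ev
  i1 <- which(ev$channels$axis == "tangential_1")
  i2 <- which(ev$channels$axis == "tangential_2")
  s2 <- ev$channels$sensor_id[i2]
  i1 <- i1[match(s2, ev$channels$sensor_id[i1])]
  ev35$mean[i1[1], ] <- 3; ev35$mean[i2[1], ] <- 4
  expect_equal(unname(tangential_norm(ev35)$mean[1, 1]), 5)
  ev35$mean[i2[1], ] <- 0
  expect_equal(unname(tangential_norm(ev35)$mean[1, 1]), 3)

  # invariance under rotation of the tangential frame
  th <- 0.83
  evr <- ev
  evr$mean[i1, ] <- cos(th) * ev$mean[i1, ] - sin(th) * ev$mean[i2, ]
  evr$mean[i2, ] <- sin(th) * ev$mean[i1, ] + cos(th) * ev$mean[i2, ]
  expect_equal(tangential_norm(evr)$mean, tn$mean, tolerance = 1e-9)

  # commutes with common positive channel scaling
  evs <- ev; evs$mean <- ev$mean * 2.5
  expect_equal(tangential_norm(evs)$mean, 2.5 * tn$mean, tolerance = 1e-12)
})

test_that("evoked metrics: peak, scale invariance, explicit null", {
  rec <- generate_evoked_recording(silent_sim(duration = 30), arr)
  ev <- pick_axis(average_epochs(baseline_correct(make_epochs(rec))), "radial")
  m <- evoked_metrics(ev)
  expect_tibble_row(m)
  expect_lt(abs(m$latency_s - 0.26), 2 / 300)

  # single-channel unit bump
  ev1 <- ev
  ev1$mean <- matrix(0, 1, length(ev$times))
  ev1$channels <- ev$channels[1, ]
  j <- which.min(abs(ev$times - 0.26))
  ev1$mean[1, j] <- 1
  ev1$mean[1, ev$times < 0] <- 1e-6 * rnorm(sum(ev$times < 0))  # nonzero baseline sd
  m1 <- evoked_metrics(ev1)
  expect_equal(m1$latency_s, ev$times[j])
  expect_equal(m1$amplitude, 1)

  # scaling: amplitude scales, latency and snr unchanged
  evk <- ev; evk$mean <- ev$mean * 4
  mk <- evoked_metrics(evk)
  expect_equal(mk$latency_s, m$latency_s)
  expect_equal(mk$amplitude, 4 * m$amplitude, tolerance = 1e-12)

  # with noise present the SNR is finite and scale-invariant
  recn <- generate_evoked_recording(fast_sim(duration = 30), arr)
  evn <- pick_axis(average_epochs(baseline_correct(make_epochs(recn))), "radial")
  mn <- evoked_metrics(evn)
  evn2 <- evn; evn2$mean <- evn$mean * 7
  expect_equal(evoked_metrics(evn2)$snr, mn$snr, tolerance = 1e-9)

  # all-zero evoked: explicit NA row
  ev0 <- ev; ev0$mean[] <- 0
  m0 <- evoked_metrics(ev0)
  expect_true(is.na(m0$latency_s) && is.na(m0$amplitude))

  # rms-peak variant agrees on t* for this clean response
  expect_equal(evoked_metrics(ev, pc_method = "rms")$latency_s, m$latency_s)
})

test_that("peak latency is recovered within 2 samples (median over seeds) at default noise", {
  full_arr <- make_sensor_array(27, 0.065, 20, seed = 1)
  errs <- vapply(1:8, function(s) {
    cfg <- sim_config(sampling_rate = 600, duration = 120, seed = 300 + s)
    rec <- generate_evoked_recording(cfg, full_arr)
    rec <- filter_bandpass(rec, 1, 40)      # the analysis band of the evoked path
    ev <- pick_axis(average_epochs(baseline_correct(make_epochs(rec))), "radial")
    abs(evoked_metrics(ev)$latency_s - 0.26) * 600
  }, numeric(1))
  expect_lte(median(errs), 2)
})
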