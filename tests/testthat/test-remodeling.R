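# Biochemical rewrite rules: polymerization geometry and rates, nucleotide
# dynamics, branching/debranching, capping, cofilin modes, bundling gates,
# angle-gated breaking, and Aip1 severing.

# a straight filament state with a huge membrane (no membrane coupling)
chain_state <- function(n = 4, p = resolve_params(), seed = 1) {
  make_fixture("straight_filament", seed, p, n = n)
}

test_that("barbed elongation continues the filament and retires the old end", {
  p <- resolve_params()
  p$internal$sigma_theta <- 0          # deterministic geometry
  S <- chain_state(2, p)
  rules <- build_ruleset(p)
  ids <- spinedgg:::live_nodes(S)
  tb <- enumerate_instances(S, rules$elongate_barbed)
  expect_equal(nrow(tb), 1)
  set.seed(1)
  fire_instance(S, rules$elongate_barbed, tb[1, , drop = FALSE])
  ids2 <- spinedgg:::live_nodes(S)
  expect_equal(length(ids2), 3)
  nid <- setdiff(ids2, ids)
  expect_equal(c(S$x[nid], S$y[nid]), c(2, 0))   # zero-angle continuation
  expect_equal(S$kind[ids[2]], spinedgg:::KIND_INTERIOR)
  expect_equal(S$kind[nid], spinedgg:::KIND_BARBED)
  check_state(S, containment = FALSE)
})

test_that("a quarter-turn rotation places the new node sideways", {
  # the elongation position rule is x3 = x2 + R(theta) (x2 - x1)
  expect_equal(as.numeric(c(1, 0) + spinedgg:::rot2(pi / 2) %*% c(1, 0)),
               c(1, 1))
})

test_that("sampled elongation angles have mean 0 and the semiflexible spread", {
  p <- resolve_params()
  S <- chain_state(2, p)
  rules <- build_ruleset(p)
  id <- spinedgg:::live_nodes(S)[2]
  pools0 <- S$pools
  set.seed(12)
  angs <- replicate(1e4, {
    tb <- spinedgg:::rule_elongate_barbed()$enumerate(S)
    fire_instance(S, rules$elongate_barbed, list(id = id, prop = tb$prop[1]))
    nid <- S$nxt[id]
    a <- atan2(S$y[nid] - S$y[id], S$x[nid] - S$x[id])
    spinedgg:::node_del(S, nid)
    S$kind[id] <- spinedgg:::KIND_BARBED
    S$pools <- pools0
    a
  })
  sg <- p$internal$sigma_theta
  expect_lt(abs(mean(angs)), 3 * sg / sqrt(1e4))
  expect_lt(abs(stats::sd(angs) - sg) / sg, 0.03)
})

test_that("retraction removes the end, restores the pool, and respects the 2-node floor", {
  p <- resolve_params()
  S <- chain_state(3, p)
  rules <- build_ruleset(p)
  ids <- spinedgg:::live_nodes(S)
  end <- ids[3]
  total0 <- sum(S$pools[c("actin", "actin_ADP")]) + spinedgg:::graph_monomers(S)
  tb <- enumerate_instances(S, rules$retract_barbed)
  expect_equal(tb$id, end)
  # fresh ATP end retracts at the ATP off rate
  expect_equal(tb$prop, p$k_barbed_off_ATP)
  fire_instance(S, rules$retract_barbed, tb[1, , drop = FALSE])
  ids2 <- spinedgg:::live_nodes(S)
  expect_equal(length(ids2), 2)
  expect_equal(S$kind[ids[2]], spinedgg:::KIND_BARBED)
  expect_equal(c(S$x[ids[2]], S$y[ids[2]]), c(1, 0))
  expect_equal(sum(S$pools[c("actin", "actin_ADP")]) +
                 spinedgg:::graph_monomers(S), total0)   # monomer bookkeeping
  # at the 2-node floor no retraction instance remains
  expect_equal(nrow(enumerate_instances(S, rules$retract_barbed)), 0)
})

test_that("an all-ADP barbed end retracts at the tabulated ADP rate", {
  p <- resolve_params()
  S <- chain_state(3, p)
  end <- spinedgg:::live_nodes(S)[3]
  S$nATP[end] <- 0L; S$nADP[end] <- p$N_CG
  tb <- enumerate_instances(S, spinedgg:::rule_retract_barbed())
  expect_equal(tb$prop, 7.2)           # k_barbed_off_ADP
})

test_that("pointed-end elongation mirrors the barbed geometry", {
  p <- resolve_params()
  p$internal$sigma_theta <- 0
  S <- chain_state(2, p)
  rules <- build_ruleset(p)
  tb <- enumerate_instances(S, rules$elongate_pointed)
  expect_equal(nrow(tb), 1)
  set.seed(2)
  fire_instance(S, rules$elongate_pointed, tb[1, , drop = FALSE])
  ids <- spinedgg:::live_nodes(S)
  nid <- ids[3]
  expect_equal(c(S$x[nid], S$y[nid]), c(-1, 0))  # continues opposite barbed
  expect_equal(S$kind[nid], spinedgg:::KIND_POINTED)
})

test_that("turnover drifts the filament toward the barbed direction", {
  p <- resolve_params()
  S <- chain_state(4, p)
  rules <- build_ruleset(p)[c("elongate_barbed", "retract_pointed")]
  set.seed(6)
  tip0 <- max(S$x[spinedgg:::live_nodes(S)])
  for (i in 1:300) ssa_step(S, rules)
  ids <- spinedgg:::live_nodes(S)
  expect_gt(max(S$x[ids]), tip0)                 # barbed front advanced
  expect_gt(mean(S$x[ids]), 1.5)                 # centroid moved barbed-ward
})

test_that("nucleotide rules race at the tabulated per-monomer rates", {
  p <- resolve_params()
  S <- chain_state(3, p)
  ids <- spinedgg:::live_nodes(S)
  tb <- enumerate_instances(S, spinedgg:::rule_hydrolysis())
  expect_equal(tb$prop, rep(p$N_CG * 0.35, 3))   # 12 ATP monomers each
  # no Pi-release instances while nothing is in the ADP+Pi state
  expect_equal(nrow(enumerate_instances(S, spinedgg:::rule_pi_release())), 0)
  S$nATP[ids] <- 0L; S$nPi[ids] <- p$N_CG
  tb2 <- enumerate_instances(S, spinedgg:::rule_pi_release())
  expect_equal(tb2$prop, rep(p$N_CG * p$k_Pi, 3))
  # adjacent cofilin accelerates Pi release ~5.8-fold
  S$ncof[ids[1]] <- p$N_CG
  tb3 <- enumerate_instances(S, spinedgg:::rule_pi_release())
  accel <- tb3$prop[tb3$id == ids[2]] / (p$N_CG * p$k_Pi)
  expect_equal(accel, 0.035 / 0.006, tolerance = 1e-9)
})

test_that("branch nucleation seeds daughters near the Arp2/3 angle", {
  p <- resolve_params()
  S <- chain_state(3, p)
  rules <- build_ruleset(p)
  id <- spinedgg:::live_nodes(S)[2]
  pools0 <- S$pools
  set.seed(8)
  n <- 4000
  angs <- replicate(n, {
    fire_instance(S, rules$branch_nucleate, list(id = id, prop = 1))
    d <- S$brn[id]
    a <- atan2(S$y[d] - S$y[id], S$x[d] - S$x[id])
    spinedgg:::node_del(S, d)
    S$kind[id] <- spinedgg:::KIND_INTERIOR
    S$theta_branch[id] <- 0
    S$pools <- pools0
    a
  })
  expect_lt(abs(mean(abs(angs)) * 180 / pi - 70),
            3 * p$internal$sigma_theta * 180 / pi / sqrt(n))
  frac_pos <- mean(angs > 0)
  expect_lt(abs(frac_pos - 0.5), 3 * sqrt(0.25 / n))   # side split 50/50
})

test_that("cofilin on the parent vetoes branch nucleation", {
  p <- resolve_params()
  S <- chain_state(3, p)
  id <- spinedgg:::live_nodes(S)[2]
  S$ncof[id] <- p$N_CG
  tb <- enumerate_instances(S, spinedgg:::rule_branch())
  expect_false(id %in% tb$id)
})

test_that("debranching rate rises ~50-fold with full cofilin occupancy", {
  p <- resolve_params()
  S <- make_fixture("branched_Y", 1, p)
  ids <- spinedgg:::live_nodes(S)
  j <- ids[S$kind[ids] == spinedgg:::KIND_JUNCTION]
  d <- S$brn[j]
  # grow the daughter so it can debranch into a legal filament
  S$kind[d] <- spinedgg:::KIND_INTERIOR
  d2 <- spinedgg:::node_add(S, spinedgg:::KIND_BARBED,
                            S$x[d] + 0.3, S$y[d] + 0.9, nATP = p$N_CG)
  spinedgg:::link_next(S, d, d2)
  tb <- enumerate_instances(S, spinedgg:::rule_debranch())
  expect_equal(tb$prop, p$k_debranch)            # cofilin-free junction
  for (id in c(j, spinedgg:::node_neighbors(S, j)))
    S$ncof[id] <- spinedgg:::.n_mono(S, id)
  tb2 <- enumerate_instances(S, spinedgg:::rule_debranch())
  expect_equal(tb2$prop / p$k_debranch, 50, tolerance = 1e-9)
  # firing conserves node count and frees the Arp2/3
  n0 <- length(spinedgg:::live_nodes(S))
  arp0 <- S$pools[["arp23"]]
  fire_instance(S, spinedgg:::rule_debranch(), tb2[1, , drop = FALSE])
  expect_equal(length(spinedgg:::live_nodes(S)), n0)
  expect_equal(S$pools[["arp23"]], arp0 + 1)
  expect_equal(S$kind[j], spinedgg:::KIND_INTERIOR)
  expect_equal(S$kind[d], spinedgg:::KIND_POINTED)
  check_state(S, containment = FALSE)
})

test_that("capping blocks elongation and retraction until uncapped", {
  p <- resolve_params()
  S <- chain_state(3, p)
  rules <- build_ruleset(p)
  end <- spinedgg:::live_nodes(S)[3]
  S$pools[["cap"]] <- 10
  tb <- enumerate_instances(S, rules$cap_barbed)
  expect_equal(tb$id, end)
  # capping propensity is mass action in the free pool
  S$pools[["cap"]] <- 20
  tb2 <- enumerate_instances(S, rules$cap_barbed)
  expect_equal(tb2$prop, 2 * tb$prop)
  fire_instance(S, rules$cap_barbed, tb2[1, , drop = FALSE])
  expect_equal(S$kind[end], spinedgg:::KIND_CAPPED)
  expect_equal(nrow(enumerate_instances(S, rules$elongate_barbed)), 0)
  expect_equal(nrow(enumerate_instances(S, rules$retract_barbed)), 0)
  # uncapping restores the original motif
  tb3 <- enumerate_instances(S, rules$uncap_barbed)
  expect_equal(tb3$prop, p$k_cap_off)
  fire_instance(S, rules$uncap_barbed, tb3[1, , drop = FALSE])
  expect_equal(S$kind[end], spinedgg:::KIND_BARBED)
  expect_equal(nrow(enumerate_instances(S, rules$elongate_barbed)), 1)
})

test_that("cofilin binding modes follow their gates and rate ratio", {
  p <- resolve_params()
  S <- chain_state(4, p)
  ids <- spinedgg:::live_nodes(S)
  # ATP filament: no bare-binding instances
  expect_equal(nrow(enumerate_instances(S, spinedgg:::rule_cofilin_bare())), 0)
  S$nATP[ids] <- 0L; S$nADP[ids] <- p$N_CG
  tb <- enumerate_instances(S, spinedgg:::rule_cofilin_bare())
  expect_equal(nrow(tb), 4)
  # saturate one node: neighbors become cooperative-edge candidates
  S$ncof[ids[2]] <- p$N_CG
  tb2 <- enumerate_instances(S, spinedgg:::rule_cofilin_edge())
  expect_setequal(tb2$id, ids[c(1, 3)])
  # accelerated : bare per-site ratio is 17e6 : 1e4
  expect_equal(tb2$prop[1] / tb$prop[1], 17e6 / 1e4, tolerance = 1e-9)
  # flanked on both sides doubles the edge propensity
  S$ncof[ids[4]] <- p$N_CG
  tb3 <- enumerate_instances(S, spinedgg:::rule_cofilin_edge())
  expect_equal(tb3$prop[tb3$id == ids[3]], 2 * tb2$prop[tb2$id == ids[3]])
  # unbinding releases the whole node's cofilin and any bound Aip1
  S$aip1[ids[2]] <- TRUE
  cof0 <- S$pools[["cof"]]; aip0 <- S$pools[["aip1"]]
  fire_instance(S, spinedgg:::rule_cofilin_unbind(),
                list(id = ids[2], prop = p$k_cof_off))
  expect_equal(S$ncof[ids[2]], 0L)
  expect_equal(S$pools[["cof"]], cof0 + p$N_CG)
  expect_equal(S$pools[["aip1"]], aip0 + 1)
})

test_that("bundling requires the distance and angle gates", {
  p <- resolve_params()
  S <- chain_state(4, p)
  # second parallel filament 0.01 um away (0.309 internal units)
  off <- 0.01e-6 / p$internal$l0
  ncg <- p$N_CG
  ids2 <- integer(4)
  for (i in 1:4) {
    kind <- if (i == 1) spinedgg:::KIND_POINTED
            else if (i == 4) spinedgg:::KIND_BARBED
            else spinedgg:::KIND_INTERIOR
    ids2[i] <- spinedgg:::node_add(S, kind, i - 1, off, nATP = ncg)
    if (i > 1) spinedgg:::link_next(S, ids2[i - 1], ids2[i])
  }
  tb <- enumerate_instances(S, spinedgg:::rule_camkii_bind())
  expect_gt(nrow(tb), 0)                         # parallel and close: eligible
  expect_equal(unique(tb$prop),
               convert_rate(p$k_camkii_on, S$pools[["camkii"]],
                            S$area_cache, p))
  # bind and check the link carries the current separation as rest length
  fire_instance(S, spinedgg:::rule_camkii_bind(), tb[1, , drop = FALSE])
  lk <- which(S$bl_alive)
  expect_equal(length(lk), 1)
  expect_equal(S$bl_rest[lk], off, tolerance = 1e-9)
  # unbinding propensity is the tabulated off rate (mean lifetime ~4.35 s)
  tb2 <- enumerate_instances(S, spinedgg:::rule_camkii_unbind())
  expect_equal(tb2$prop, 0.23)
  fire_instance(S, spinedgg:::rule_camkii_unbind(), tb2[1, , drop = FALSE])
  expect_equal(sum(S$bl_alive), 0)
  # rotate the second filament to 20 degrees: angle gate closes
  th <- 20 * pi / 180
  for (i in 1:4) {
    S$x[ids2[i]] <- (i - 1) * cos(th)
    S$y[ids2[i]] <- off + (i - 1) * sin(th)
  }
  tb3 <- enumerate_instances(S, spinedgg:::rule_camkii_bind())
  # surviving pairs (if any) involve only the near-origin nodes still within
  # distance; none should join the rotated filament at 20 degrees
  expect_equal(nrow(tb3), 0)
})

test_that("breaking eligibility follows the three angle thresholds", {
  p <- resolve_params()
  build_bent <- function(theta_deg, cof2 = 0, cof3 = 0) {
    # pointed - interior(bend here) - interior - barbed, bend angle at node 2
    S <- chain_state(2, p)
    ids <- spinedgg:::live_nodes(S)
    th <- theta_deg * pi / 180
    d <- c(cos(th), sin(th))
    id3 <- spinedgg:::node_add(S, spinedgg:::KIND_INTERIOR,
                               1 + d[1], d[2], nATP = p$N_CG)
    id4 <- spinedgg:::node_add(S, spinedgg:::KIND_BARBED,
                               1 + 2 * d[1], 2 * d[2], nATP = p$N_CG)
    spinedgg:::link_next(S, ids[2], id3)
    spinedgg:::link_next(S, id3, id4)
    S$kind[ids[2]] <- spinedgg:::KIND_INTERIOR
    S$ncof[ids[2]] <- cof2
    S$ncof[id3] <- cof3
    spinedgg:::update_angles(S, c(ids, id3, id4))
    S
  }
  n_inst <- function(S) nrow(enumerate_instances(S, spinedgg:::rule_break()))
  expect_equal(n_inst(build_bent(60)), 1)            # bare, 60 > 57
  expect_equal(n_inst(build_bent(50)), 0)            # bare, 50 < 57
  expect_equal(n_inst(build_bent(40, cof2 = 12)), 1) # boundary, 40 > 31
  expect_equal(n_inst(build_bent(40)), 0)            # same geometry, bare
  expect_equal(n_inst(build_bent(60, cof2 = 12, cof3 = 12)), 0) # cofilactin needs 73
  expect_equal(n_inst(build_bent(75, cof2 = 12, cof3 = 12)), 1)
  expect_equal(n_inst(build_bent(0)), 0)             # straight never breaks
  # firing splits the filament and conserves nodes
  S <- build_bent(60)
  n0 <- length(spinedgg:::live_nodes(S))
  tb <- enumerate_instances(S, spinedgg:::rule_break())
  fire_instance(S, spinedgg:::rule_break(), tb[1, , drop = FALSE])
  expect_equal(length(spinedgg:::live_nodes(S)), n0)
  kinds <- S$kind[spinedgg:::live_nodes(S)]
  expect_equal(sum(kinds == spinedgg:::KIND_BARBED), 2)
  expect_equal(sum(kinds == spinedgg:::KIND_POINTED), 2)
  check_state(S, containment = FALSE)
})

test_that("Aip1 binds cofilactin only and severing caps the new barbed end", {
  p <- resolve_params()
  S <- chain_state(4, p)
  ids <- spinedgg:::live_nodes(S)
  S$pools[["aip1"]] <- 5
  expect_equal(nrow(enumerate_instances(S, spinedgg:::rule_aip1_bind())), 0)
  S$nATP[ids[2]] <- 0L; S$nADP[ids[2]] <- p$N_CG
  S$ncof[ids[2]] <- p$N_CG
  tb <- enumerate_instances(S, spinedgg:::rule_aip1_bind())
  expect_equal(tb$id, ids[2])
  fire_instance(S, spinedgg:::rule_aip1_bind(), tb[1, , drop = FALSE])
  expect_true(S$aip1[ids[2]])
  n0 <- length(spinedgg:::live_nodes(S))
  mono0 <- spinedgg:::graph_monomers(S)
  tb2 <- enumerate_instances(S, spinedgg:::rule_aip1_sever())
  expect_equal(tb2$prop, 1.43)
  fire_instance(S, spinedgg:::rule_aip1_sever(), tb2[1, , drop = FALSE])
  expect_equal(length(spinedgg:::live_nodes(S)), n0)
  expect_equal(spinedgg:::graph_monomers(S), mono0)
  expect_true(S$capA[ids[2]])                        # Aip1-capped barbed end
  expect_equal(S$kind[ids[2]], spinedgg:::KIND_CAPPED)
  expect_equal(S$kind[ids[3]], spinedgg:::KIND_POINTED)
  # the Aip1 cap dissociates through the uncapping rule, freeing Aip1
  aip0 <- S$pools[["aip1"]]
  tb3 <- enumerate_instances(S, spinedgg:::rule_uncap())
  fire_instance(S, spinedgg:::rule_uncap(), tb3[1, , drop = FALSE])
  expect_equal(S$pools[["aip1"]], aip0 + 1)
  expect_equal(S$kind[ids[2]], spinedgg:::KIND_BARBED)
  check_state(S, containment = FALSE)
})
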