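test_that("lattice counts, determinism and degree structure are correct", {
  net <- build_lattice(30, 30, frac_inhibitory = 0.2, seed = 4)
  expect_equal(net$n, 900)
  expect_equal(sum(!net$is_exc), 180)

  # determinism: same seed, identical edges and types
  net2 <- build_lattice(30, 30, frac_inhibitory = 0.2, seed = 4)
  expect_identical(net$exc_edges, net2$exc_edges)
  expect_identical(net$cell_type, net2$cell_type)

  # degree bounds under default neighborhoods
  indeg_e <- tabulate(net$exc_edges$post, nbins = net$n)
  indeg_i <- tabulate(net$inh_edges$post, nbins = net$n)
  expect_lte(max(indeg_e), 24)
  expect_lte(max(indeg_i), 8)
})

test_that("every in-edge comes from the correct periodic neighborhood", {
  # exhaustive brute-force enumeration on two lattice sizes
  for (dims in list(c(5, 5), c(7, 6))) {
    nr <- dims[1]; nc <- dims[2]
    net <- build_lattice(nr, nc, frac_inhibitory = 0.3, seed = 2)
    pos <- function(i) c((i - 1) %/% nc + 1, (i - 1) %% nc + 1)
    tor_d <- function(a, b, n) min((a - b) %% n, (b - a) %% n)
    check_edges <- function(edges, h, pre_exc) {
      for (k in seq_len(nrow(edges))) {
        pp <- pos(edges$pre[k]); pq <- pos(edges$post[k])
        expect_lte(tor_d(pp[1], pq[1], nr), h)
        expect_lte(tor_d(pp[2], pq[2], nc), h)
        expect_false(edges$pre[k] == edges$post[k])
        expect_equal(net$is_exc[edges$pre[k]], pre_exc)
      }
      # completeness: every qualifying neighbor projects exactly once
      for (post in seq_len(net$n)) {
        got <- sort(edges$pre[edges$post == post])
        want <- setdiff(which(vapply(seq_len(net$n), function(pre) {
          pp <- pos(pre); pq <- pos(post)
          net$is_exc[pre] == pre_exc &&
            tor_d(pp[1], pq[1], nr) <= h && tor_d(pp[2], pq[2], nc) <= h
        }, logical(1))), post)
        expect_equal(got, want)
      }
    }
    check_edges(net$exc_edges, 2, TRUE)
    check_edges(net$inh_edges, 1, FALSE)
  }
})

test_that("parameter randomization has the configured dispersion", {
  net <- build_lattice(30, 30, seed = 1)
  # cv = 0 leaves the means untouched
  net0 <- sample_parameters(net, cv = 0, seed = 9)
  expect_equal(net0$w_exc, net$w_exc)

  net5 <- sample_parameters(net, cv = 0.05, seed = 9)
  emp_cv <- sd(net5$w_exc) / mean(net5$w_exc)
  se <- 0.05 / sqrt(2 * length(net5$w_exc))
  expect_lt(abs(emp_cv - 0.05), 3 * se + 0.002)
  expect_true(all(net5$w_exc > 0))
  expect_true(all(net5$w_inh > 0))

  # huge cv exercises the redraw-at-zero rule
  net_big <- sample_parameters(net, cv = 1.5, seed = 10)
  expect_true(all(net_big$w_exc > 0))
})

test_that("subregions are disjoint 11x11 blocks; degenerate cases handled", {
  net <- build_lattice(30, 30, seed = 1)
  subs <- subregion_indices(net, k = 4, size = 11)
  expect_length(subs, 4)
  for (s in subs) expect_length(s, 121)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_length(intersect(subs[[i]], subs[[j]]), 0)
  }
  all_idx <- subregion_indices(net, k = 1, size = 30)[[1]]
  expect_equal(sort(all_idx), 1:900)
  expect_error(subregion_indices(net, k = 4, size = 20), "overlap|cannot")
})

test_that("network export/import round-trips through delimited tables", {
  net <- tiny_net(seed = 3)
  nf <- tempfile(fileext = ".tsv"); ef <- tempfile(fileext = ".tsv")
  write_network(net, nf, ef)
  back <- read_network(nf, ef)
  expect_equal(back$n, net$n)
  expect_equal(back$is_exc, net$is_exc)
  expect_equal(back$params$e_ss, net$params$e_ss, tolerance = 1e-9)
  o1 <- order(net$exc_edges$pre, net$exc_edges$post)
  o2 <- order(back$exc_edges$pre, back$exc_edges$post)
  expect_equal(net$exc_edges[o1, ], back$exc_edges[o2, ],
               ignore_attr = TRUE)
  expect_equal(net$w_exc[o1], back$w_exc[o2], tolerance = 1e-9)
  unlink(c(nf, ef))
})

test_that("a lattice smaller than the neighborhood is rejected", {
  expect_error(build_lattice(4, 4), "smaller than")
})
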