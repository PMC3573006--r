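#' Build the 2D lattice network
#'
#' Excitatory and inhibitory neurons are placed uniformly at random on an
#' `n_rows` x `n_cols` lattice (default 30 x 30 = 900 neurons, 20%
#' inhibitory). Every neuron receives one synapse from each excitatory
#' neuron in its 5 x 5 neighborhood and from each inhibitory neuron in its
#' 3 x 3 neighborhood, with periodic (toroidal) boundary conditions and no
#' self-connections. Neighborhood sizes are configurable for connectivity
#' sweeps.
#'
#' @param n_rows,n_cols lattice dimensions (each at least the largest
#'   neighborhood size).
#' @param frac_inhibitory fraction of inhibitory neurons in (0, 1).
#' @param seed integer seed; networks are reproducible given
#'   `(arguments, seed)`.
#' @param exc_nbhd,inh_nbhd odd neighborhood edge lengths for excitatory and
#'   inhibitory projections (defaults 5 and 3).
#' @param kinetics a [synapse_kinetics()] providing the mean weights.
#' @return A list of class `lattice_network` with per-neuron positions and
#'   types, edge lists (`exc_edges`, `inh_edges` with columns `pre`, `post`),
#'   per-edge weights (set to the class means; see [sample_parameters()]),
#'   and per-neuron Izhikevich parameters (set to the type means).
#' @export
build_lattice <- function(n_rows = 30, n_cols = 30, frac_inhibitory = 0.2,
                          seed = 1, exc_nbhd = 5, inh_nbhd = 3,
                          kinetics = synapse_kinetics()) {
  stopifnot(
    frac_inhibitory > 0, frac_inhibitory < 1,
    exc_nbhd %% 2 == 1, inh_nbhd %% 2 == 1
  )
  if (n_rows < max(exc_nbhd, inh_nbhd) || n_cols < max(exc_nbhd, inh_nbhd)) {
    stop("lattice smaller than the synaptic neighborhood")
  }
  n <- n_rows * n_cols
  n_inh <- round(frac_inhibitory * n)
  is_exc <- rep(TRUE, n)
  is_exc[with_seed(seed, sample.int(n, n_inh))] <- FALSE

  idx <- seq_len(n) - 1L
  row <- idx %/% n_cols + 1L
  col <- idx %% n_cols + 1L

  edges_for <- function(nbhd, pre_is_exc) {
    h <- (nbhd - 1L) %/% 2L
    off <- expand.grid(dr = -h:h, dc = -h:h)
    pre_list <- vector("list", nrow(off))
    post_list <- vector("list", nrow(off))
    for (k in seq_len(nrow(off))) {
      if (off$dr[k] == 0 && off$dc[k] == 0) next  # no self-edges
      pr <- ((row - 1L + off$dr[k]) %% n_rows) * n_cols +
        ((col - 1L + off$dc[k]) %% n_cols) + 1L
      keep <- is_exc[pr] == pre_is_exc
      pre_list[[k]] <- pr[keep]
      post_list[[k]] <- seq_len(n)[keep]
    }
    data.frame(pre = unlist(pre_list), post = unlist(post_list))
  }

  exc_edges <- edges_for(exc_nbhd, TRUE)
  inh_edges <- edges_for(inh_nbhd, FALSE)

  pe <- neuron_params("excitatory")
  pi_ <- neuron_params("inhibitory")
  params <- data.frame(
    a = ifelse(is_exc, pe$a, pi_$a), b = ifelse(is_exc, pe$b, pi_$b),
    c = ifelse(is_exc, pe$c, pi_$c), d = ifelse(is_exc, pe$d, pi_$d),
    e_ss = ifelse(is_exc, pe$e_ss, pi_$e_ss)
  )

  net <- list(
    n_rows = n_rows, n_cols = n_cols, n = n,
    row = row, col = col, is_exc = is_exc,
    cell_type = ifelse(is_exc, "E", "I"),
    exc_edges = exc_edges, inh_edges = inh_edges,
    w_exc = rep(kinetics$w_exc_mean, nrow(exc_edges)),
    w_inh = rep(kinetics$w_inh_mean, nrow(inh_edges)),
    params = params, kinetics = kinetics,
    k_e = pe$k_e, tau_r = pe$tau_r,
    exc_nbhd = exc_nbhd, inh_nbhd = inh_nbhd,
    rng_seed = seed
  )
  class(net) <- "lattice_network"
  net
}

#' @export
print.lattice_network <- function(x, ...) {
  cat(sprintf(
    "<lattice_network> %d x %d (%d neurons: %d E, %d I)\n",
    x$n_rows, x$n_cols, x$n, sum(x$is_exc), sum(!x$is_exc)
  ))
  cat(sprintf(
    "  excitatory edges: %d (%dx%d nbhd)   inhibitory edges: %d (%dx%d nbhd)\n",
    nrow(x$exc_edges), x$exc_nbhd, x$exc_nbhd,
    nrow(x$inh_edges), x$inh_nbhd, x$inh_nbhd
  ))
  cat(sprintf("  seed: %d\n", x$rng_seed))
  invisible(x)
}

#' Randomize neuron parameters and synaptic weights
#'
#' Per-neuron Izhikevich parameters (and the steady-state excitability) and
#' per-edge weights are drawn from normal distributions centered on their
#' type means with standard deviation `cv` times the mean magnitude.
#' Non-positive weight draws are redrawn (documented truncation rule); with
#' the default `cv = 0.05` redraws are practically never needed.
#'
#' @param net a [build_lattice()] network.
#' @param cv coefficient of variation (default 0.05).
#' @param seed integer seed.
#' @return The network with randomized `params`, `w_exc`, `w_inh`.
#' @export
sample_parameters <- function(net, cv = 0.05, seed = 1) {
  stopifnot(inherits(net, "lattice_network"), cv >= 0)
  if (cv == 0) return(net)
  with_seed(seed, {
    jitter_par <- function(mu) rnorm(length(mu), mu, cv * abs(mu))
    for (nm in c("a", "b", "c", "d", "e_ss")) {
      net$params[[nm]] <- jitter_par(net$params[[nm]])
    }
    draw_w <- function(k, mu) {
      w <- rnorm(k, mu, cv * mu)
      bad <- which(w <= 0)
      while (length(bad) > 0) {
        w[bad] <- rnorm(length(bad), mu, cv * mu)
        bad <- bad[w[bad] <= 0]
      }
      w
    }
    net$w_exc <- draw_w(nrow(net$exc_edges), net$kinetics$w_exc_mean)
    net$w_inh <- draw_w(nrow(net$inh_edges), net$kinetics$w_inh_mean)
  })
  net$param_cv <- cv
  net
}

#' Non-overlapping square subregions of the lattice
#'
#' Returns `k` disjoint `size` x `size` blocks of neuron indices. For the
#' default `k = 4`, `size = 11` on a 30 x 30 lattice the blocks are centered
#' in the four quadrants, mimicking multiple recording electrodes.
#'
#' @param net a [build_lattice()] network.
#' @param k number of blocks (1 or a perfect-square-arrangeable count).
#' @param size block edge length.
#' @return list of integer vectors of neuron indices (each of length
#'   `size^2`).
#' @export
subregion_indices <- function(net, k = 4, size = 11) {
  stopifnot(inherits(net, "lattice_network"), k >= 1,
            size <= min(net$n_rows, net$n_cols))
  g <- ceiling(sqrt(k))
  if (g * size > min(net$n_rows, net$n_cols) && k > 1) {
    stop("cannot place ", k, " non-overlapping ", size, "x", size, " blocks")
  }
  centers_r <- round((seq_len(g) - 0.5) * net$n_rows / g)
  centers_c <- round((seq_len(g) - 0.5) * net$n_cols / g)
  h <- (size - 1) / 2
  out <- vector("list", k)
  b <- 0L
  for (ir in seq_len(g)) {
    for (ic in seq_len(g)) {
      if (b >= k) break
      b <- b + 1L
      r0 <- round(centers_r[ir] - h)
      c0 <- round(centers_c[ic] - h)
      r0 <- max(1, min(net$n_rows - size + 1, r0))
      c0 <- max(1, min(net$n_cols - size + 1, c0))
      rows <- r0:(r0 + size - 1)
      cols <- c0:(c0 + size - 1)
      out[[b]] <- as.integer(outer((rows - 1) * net$n_cols, cols,
                                   FUN = "+"))
    }
  }
  for (i in seq_along(out)) {
    for (j in seq_len(i - 1)) {
      if (length(intersect(out[[i]], out[[j]])) > 0) {
        stop("subregion blocks overlap; reduce k or size")
      }
    }
  }
  out
}

#' Export / import a network as two delimited tables
#'
#' Nodes: `id,row,col,type,a,b,c,d,e_ss`; edges: `pre,post,class,weight`.
#'
#' @param net a network.
#' @param nodes_file,edges_file file paths.
#' @return `write_network` returns the paths invisibly; `read_network`
#'   a reconstructed `lattice_network`.
#' @export
write_network <- function(net, nodes_file, edges_file) {
  nodes <- data.frame(
    id = seq_len(net$n), row = net$row, col = net$col,
    type = net$cell_type, net$params
  )
  edges <- rbind(
    data.frame(net$exc_edges, class = "exc", weight = net$w_exc),
    data.frame(net$inh_edges, class = "inh", weight = net$w_inh)
  )
  write.table(nodes, nodes_file, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(edges, edges_file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(nodes_file, edges_file))
}

#' @rdname write_network
#' @param kinetics kinetics to attach on import.
#' @export
read_network <- function(nodes_file, edges_file,
                         kinetics = synapse_kinetics()) {
  nodes <- read.table(nodes_file, header = TRUE, sep = "\t")
  edges <- read.table(edges_file, header = TRUE, sep = "\t")
  nodes <- nodes[order(nodes$id), ]
  n_rows <- max(nodes$row)
  n_cols <- max(nodes$col)
  exc <- edges[edges$class == "exc", ]
  inh <- edges[edges$class == "inh", ]
  pe <- neuron_params("excitatory")
  net <- list(
    n_rows = n_rows, n_cols = n_cols, n = nrow(nodes),
    row = nodes$row, col = nodes$col, is_exc = nodes$type == "E",
    cell_type = nodes$type,
    exc_edges = data.frame(pre = exc$pre, post = exc$post),
    inh_edges = data.frame(pre = inh$pre, post = inh$post),
    w_exc = exc$weight, w_inh = inh$weight,
    params = nodes[, c("a", "b", "c", "d", "e_ss")],
    kinetics = kinetics, k_e = pe$k_e, tau_r = pe$tau_r,
    exc_nbhd = NA_integer_, inh_nbhd = NA_integer_,
    rng_seed = NA_integer_
  )
  class(net) <- "lattice_network"
  net
}
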