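# Independent reference implementations used to cross-check the compiled
# kernels.  These deliberately share nothing with the package internals
# except the public pair_noise() stream.

# O(N^2) DPD forces in plain R: conservative, dissipative, random, bond.
brute_forces <- function(snap, ff, dt, seed, step) {
  pos <- snap$positions
  vel <- snap$velocities
  box <- snap$box
  n <- nrow(pos)
  tab <- ff$table
  code <- match(snap$species, tab$species)
  FC <- FD <- FR <- FB <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- pos[i, ] - pos[j, ]
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      if (r < tab$r_c && r > 0) {
        e <- d / r
        w <- 1 - r / tab$r_c
        a <- tab$a[code[i], code[j]]
        fc <- a * w * e
        rv <- sum(e * (vel[i, ] - vel[j, ]))
        fd <- -tab$gamma * w^2 * rv * e
        fr <- tab$sigma * w * pair_noise(seed, step, i, j) / sqrt(dt) * e
        FC[i, ] <- FC[i, ] + fc; FC[j, ] <- FC[j, ] - fc
        FD[i, ] <- FD[i, ] + fd; FD[j, ] <- FD[j, ] - fd
        FR[i, ] <- FR[i, ] + fr; FR[j, ] <- FR[j, ] - fr
      }
    }
  }
  if (nrow(snap$bonds) > 0) {
    for (b in seq_len(nrow(snap$bonds))) {
      i <- snap$bonds[b, 1]; j <- snap$bonds[b, 2]
      d <- pos[i, ] - pos[j, ]
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      if (r > 0) {
        f <- -ff$spring_k * (r - ff$spring_r0) * d / r
        FB[i, ] <- FB[i, ] + f; FB[j, ] <- FB[j, ] - f
      }
    }
  }
  list(conservative = FC, dissipative = FD, random = FR, bond = FB)
}

# Connected components of an adjacency list by breadth-first search.
bfs_components <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue) > 0) {
        v <- queue[[1]]; queue <- queue[-1]
        for (u in adj[[v]]) {
          if (comp[u] == 0L) { comp[u] <- cur; queue <- c(queue, u) }
        }
      }
    }
  }
  comp
}

# Canonical form of a partition: renumber cluster labels by first occurrence.
canonical_partition <- function(memb) {
  match(memb, unique(memb))
}

# A tiny two-bead snapshot at a given separation along x.
two_bead_snapshot <- function(r, box = 10, species = c("W", "W"),
                              velocities = matrix(0, 2, 3), bonds = NULL) {
  pos <- rbind(c(1, 5, 5), c(1 + r, 5, 5))
  snapshot(box, pos, velocities, species, 1:2,
           bonds = if (is.null(bonds)) matrix(integer(0), 0, 2) else bonds)
}

water_ff <- function(...) force_field(interaction_table("W", matrix(0, 1, 1)), ...)

# Synthetic rdf_profile with a constant density-weighted value.
flat_profile <- function(rho, delta_r = 0.05, r_max = 2) {
  nbin <- ceiling(r_max / delta_r)
  r <- (seq_len(nbin) - 0.5) * delta_r
  out <- tibble::tibble(r = r, rho_g = rep(rho, nbin))
  structure(out, ref_species = "A", target_species = "B",
            delta_r = delta_r, n_frames = 1L, box = 100,
            class = c("rdf_profile", class(out)))
}
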