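## Independent oracles used across the suite. These deliberately take the
## slow, obviously-correct route (exhaustive enumeration, closed forms) and
## share no code with the package implementations they check.

## all-windows minimum mean, by explicit enumeration
brute_min_window <- function(readings, w) {
  n <- length(readings)
  min(vapply(seq_len(n - w + 1),
             function(i) mean(readings[i:(i + w - 1)]), numeric(1)))
}

## textbook closed-form simple OLS: slope, se, t, p, r2
brute_ols <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tstat <- slope / se
  list(intercept = intercept, slope = slope, se = se, t = tstat,
       p = 2 * pt(-abs(tstat), n - 2),
       r2 = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

## d-separation by moralized ancestral graph + reachability
## edges: data.frame(from, to); x, y: nodes; cond: character vector
dsep_oracle <- function(nodes, edges, x, y, cond) {
  parents <- function(v) edges$from[edges$to == v]
  ## ancestors of x, y and cond
  anc <- unique(c(x, y, cond))
  repeat {
    more <- unique(unlist(lapply(anc, parents)))
    new <- setdiff(more, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  es <- edges[edges$from %in% anc & edges$to %in% anc, , drop = FALSE]
  ## moralize: undirected edges for every directed edge + marry parents
  und <- rbind(es[, c("from", "to")],
               do.call(rbind, lapply(unique(es$to), function(v) {
                 pa <- parents(v)
                 pa <- pa[pa %in% anc]
                 if (length(pa) < 2) return(NULL)
                 cmb <- t(combn(pa, 2))
                 data.frame(from = cmb[, 1], to = cmb[, 2])
               })))
  ## delete conditioned nodes, test connectivity x -- y
  keep <- setdiff(anc, cond)
  if (!(x %in% keep) || !(y %in% keep)) return(TRUE)
  und <- und[und$from %in% keep & und$to %in% keep, , drop = FALSE]
  reach <- x
  repeat {
    nb <- unique(c(und$to[und$from %in% reach], und$from[und$to %in% reach]))
    new <- setdiff(nb, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  !(y %in% reach)
}

## every DAG on k topologically-labelled nodes (edges only i -> j, i < j):
## returns a list of data.frame(from, to)
all_dags <- function(k, node_names = paste0("N", seq_len(k))) {
  pairs <- t(combn(seq_len(k), 2))
  m <- nrow(pairs)
  lapply(0:(2^m - 1), function(mask) {
    on <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    data.frame(from = node_names[pairs[on, 1]],
               to = node_names[pairs[on, 2]],
               stringsAsFactors = FALSE)
  })
}

## small synthetic record sets with in-band masses for the three modelling
## stages; used when a test needs records without the full generator
make_records <- function(n, sites, temp, slope = 0, site_re = NULL,
                         shape = 400, intercept = 95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- length(sites)
  if (is.null(site_re)) site_re <- rep(0, ns)
  idx <- rep(seq_len(ns), each = n)
  sex <- sample(c("female", "male"), n * ns, replace = TRUE)
  stage <- sample(c("subadult", "adult1", "adult2"), n * ns, replace = TRUE)
  mass_lo <- c(subadult = 16.1, adult1 = 23.1, adult2 = 29.1)
  mass_hi <- c(subadult = 22.9, adult1 = 28.9, adult2 = 36.9)
  mu <- intercept + slope * temp[idx] + 2 * (sex == "male") +
    c(subadult = 0, adult1 = 6, adult2 = 12)[stage] + site_re[idx]
  data.frame(id = seq_len(n * ns), site = sites[idx],
             year = 2022, sex = sex, stage = stage,
             body_mass = runif(n * ns, mass_lo[stage], mass_hi[stage]),
             body_length = rgamma(n * ns, shape = shape, scale = mu / shape),
             pregnant = FALSE, stringsAsFactors = FALSE)
}
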