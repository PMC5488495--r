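# Shared fixtures, built in code. Heavyweight objects are computed once per
# test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Hand-built region forest from a parent vector (NA = root); pixel sets are
# synthetic but nested, so structural operations behave as on real forests.
make_forest <- function(parent, levels = NULL) {
  n <- length(parent)
  if (is.null(levels)) {
    levels <- integer(n)
    for (i in seq_len(n)) {
      p <- parent[i]
      lvl <- 0L
      while (!is.na(p)) { lvl <- lvl + 1L; p <- parent[p] }
      levels[i] <- lvl
    }
  }
  # nested pixel sets: each node owns one pixel plus its descendants' pixels
  ch <- vector("list", n)
  for (i in seq_len(n)) if (!is.na(parent[i])) ch[[parent[i]]] <- c(ch[[parent[i]]], i)
  pix <- vector("list", n)
  fill <- function(i) {
    out <- i
    for (k in ch[[i]]) out <- c(out, fill(k))
    pix[[i]] <<- sort(out)
    out
  }
  for (r in which(is.na(parent))) fill(r)
  structure(list(
    nodes = data.frame(id = seq_len(n), parent = parent, level = levels,
                       area = lengths(pix)),
    pixels = pix, dim = c(1L, n), n_levels = 256L, polarity = "bright"),
    class = "region_forest")
}

# Random tree as a parent vector (node 1 is the root).
random_parent <- function(n) {
  if (n == 1) return(NA_integer_)
  c(NA_integer_, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
}

# Exhaustive minimization of the detection energy over all labelings that
# satisfy the non-overlap constraint (oracle for the dynamic program).
brute_force_min_energy <- function(forest, scores) {
  n <- nrow(forest$nodes)
  best <- Inf
  for (m in 0:(2^n - 1)) {
    y <- as.integer(intToBits(m)[1:n])
    if (satisfies_path_constraint(forest, y))
      best <- min(best, detection_energy(y, scores))
  }
  best
}

# Brute-force minimum-cost one-to-one assignment (oracle for the Hungarian
# matcher); returns the minimum total cost over all maximal matchings.
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n <= m) {
    perms <- gtools_permutations(m, n)
    best <- Inf
    for (i in seq_len(nrow(perms)))
      best <- min(best, sum(cost[cbind(seq_len(n), perms[i, ])]))
    best
  } else {
    brute_force_assignment(t(cost))
  }
}

# all k-permutations of 1..n (small n only)
gtools_permutations <- function(n, k) {
  if (k == 0) return(matrix(integer(0), 1, 0))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (x in remaining) rec(c(prefix, x), setdiff(remaining, x))
  }
  rec(integer(0), seq_len(n))
  do.call(rbind, out)
}

# Exhaustive component extraction by thresholding at every quantized level
# (oracle for build_forest): distinct connected components (4-connectivity
# via EBImage::bwlabel) with area within bounds, as sorted pixel-index sets.
threshold_components_oracle <- function(map, min_area, max_area,
                                        n_levels = 256L) {
  rng <- range(map)
  q <- if (rng[2] > rng[1]) (map - rng[1]) / (rng[2] - rng[1]) else map * 0
  qi <- matrix(as.integer(round(q * (n_levels - 1L))), nrow(map), ncol(map))
  comps <- new.env(parent = emptyenv())
  for (t in sort(unique(as.vector(qi)))) {
    lab <- EBImage::bwlabel(qi >= t)
    for (l in seq_len(max(lab))) {
      pixset <- sort(which(lab == l))
      if (length(pixset) < min_area || length(pixset) > max_area) next
      assign(paste(pixset, collapse = ","), TRUE, envir = comps)
    }
  }
  sort(ls(comps))
}

forest_pixel_keys <- function(forest) {
  sort(vapply(forest$pixels, function(p) paste(p, collapse = ","), ""))
}

# Nestedness check: every pair of regions in a forest is nested or disjoint.
check_nestedness <- function(forest) {
  n <- nrow(forest$nodes)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      a <- forest$pixels[[i]]; b <- forest$pixels[[j]]
      inter <- length(intersect(a, b))
      if (inter > 0 && inter != length(a) && inter != length(b)) return(FALSE)
    }
  }
  TRUE
}

# A small easy-contrast scene set plus a trained checkpoint; used by the
# end-to-end tests. Sizes are kept small so the whole suite stays fast.
mini_pipeline <- function() {
  fixture("mini_pipeline", function() {
    spec <- scene_spec_easy(image_height = 128L, image_width = 128L,
                            n_cells = 26L)
    scenes <- lapply(1:4, function(i) {
      sp <- spec; sp$seed <- 500L + i
      generate_scene(sp)
    })
    dcfg <- detector_config(
      min_area = 25L, max_area = 369L, min_diversity = 0.5,
      model = model_config(step_rule = "backtrack", sigma_floor = 0.2,
                           iters_sup = 300L, iters_joint = 200L, seed = 7L))
    prep <- lapply(scenes, function(s) cellpath:::prepare_image(s$image, dcfg))
    pool <- make_subimage_pool(scenes[1:2], seed = 3L)
    ck <- crops <- NULL
    for (attempt in 0:20) {  # skip draws whose window has only one class
      crops <- sample_crops(pool, 1L, seed = 11L + attempt)
      ck <- tryCatch(train_detector(crops, config = dcfg, prepared = prep[1:2],
                                    arm = "ss"),
                     error = function(e) NULL)
      if (!is.null(ck)) break
    }
    list(spec = spec, scenes = scenes, prep = prep, config = dcfg,
         crops = crops, checkpoint = ck)
  })
}
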