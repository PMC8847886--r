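# Shared fixtures, built in code. Heavy cohorts are created lazily and
# cached for the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_spec <- function(seed = 11, ...) {
  cohort_spec(n_mz_families = 2, n_dz_families = 2, n_sib_families = 2,
              sibs_per_family = 3, n_singles = 10, n_nodes = 10,
              n_timepoints = 60, n_sms = 12, seed = seed, ...)
}

# default desk-scale planted cohort (n = 300, 50 nodes), with netmats and
# edge matrix precomputed once
planted_fixture <- function() {
  cached("planted", function() {
    spec <- cohort_spec(seed = 42)
    cohort <- simulate_cohort(spec)
    netmats <- lapply(cohort$timeseries, partial_netmat_ridge)
    edges <- assemble_edges(netmats)
    list(spec = spec, cohort = cohort, netmats = netmats, edges = edges)
  })
}

# validity oracle for restricted permutations: role preserved pointwise and
# every family's image is exactly one same-signature family
perm_is_valid <- function(p, families) {
  role <- as.character(families$member_type)
  if (!all(role[p] == role)) return(FALSE)
  fam <- split(seq_len(nrow(families)), families$family_id)
  sig <- vapply(fam, function(idx) paste(sort(role[idx]), collapse = "+"),
                character(1))
  for (fi in seq_along(fam)) {
    img <- p[fam[[fi]]]
    hit <- vapply(fam, function(g) all(img %in% g) && length(img) == length(g),
                  logical(1))
    if (sum(hit) != 1L) return(FALSE)
    if (sig[hit] != sig[fi]) return(FALSE)
  }
  TRUE
}

# brute-force enumeration of all valid restricted permutations (tiny n only)
enumerate_valid_perms <- function(families) {
  n <- nrow(families)
  stopifnot(n <= 7)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  grid <- grid[apply(grid, 1, function(p) length(unique(p)) == n), , drop = FALSE]
  keep <- apply(grid, 1, perm_is_valid, families = families)
  grid[keep, , drop = FALSE]
}
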