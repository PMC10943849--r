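# Independent oracles used across test files. These deliberately avoid the
# package's enumeration path: congeners are generated by brute force over
# all 1024 ring-pair bit patterns and reduced under the order-8 symmetry
# group element by element.

oracle_flip <- function(pos) sort(8L - pos)

oracle_ring_str <- function(pos) {
  if (length(pos) == 0L) "0" else paste(sort(pos), collapse = "")
}

# label under the package's documented convention (ring digit strings
# compared lexicographically, bare ring "0" second), computed from scratch
oracle_label <- function(a, b) {
  sa <- oracle_ring_str(a); sb <- oracle_ring_str(b)
  if (sa == "0") paste(sb, sa, sep = "-")
  else if (sb == "0") paste(sa, sb, sep = "-")
  else if (sb < sa) paste(sb, sa, sep = "-")
  else paste(sa, sb, sep = "-")
}

# canonical label = minimum over all 8 symmetry images
oracle_canonical <- function(a, b) {
  imgs <- character(0)
  for (fa in list(sort(a), oracle_flip(a)))
    for (fb in list(sort(b), oracle_flip(b)))
      imgs <- c(imgs, oracle_label(fa, fb), oracle_label(fb, fa))
  min(imgs)
}

# all 209 canonical labels by brute force over 32 x 32 subset pairs
oracle_all_congeners <- function() {
  subsets <- lapply(0:31, function(bits) (2:6)[bitwAnd(bits, 2^(0:4)) > 0])
  labs <- character(0)
  for (a in subsets) for (b in subsets) {
    if (length(a) + length(b) == 0) next
    labs <- c(labs, oracle_canonical(a, b))
  }
  unique(labs)
}

# random congener profile over a given label set
random_profile <- function(labels, n = 5) {
  picks <- sample(labels, n)
  stats::setNames(stats::runif(n, 0.1, 5), picks)
}
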