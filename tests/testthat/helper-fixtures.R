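## Small fixtures and independent oracles used across the suite. All
## fixtures are generated in code; the oracles deliberately use different
## algorithms from the package implementation.

## a compact hairpin backbone for fast unit tests
small_backbone <- function(stem = 60L, loop = 8L, seed = 11L) {
  example_backbone(
    seed = seed, stem_length = stem, loop_length = loop,
    n_adenosines = round(0.3 * stem)
  )
}

## enzyme with neutral context and no suppression gaps at the peak; handy
## for arithmetic-level checks
plain_profile <- function(baseline = 0.3, offset = -26L, fold = 1.4,
                          suppression = default_suppression("+1"),
                          symmetric = FALSE) {
  enzyme_profile("plain",
    baseline_edit_prob = baseline,
    induction_offset = offset, induction_fold = fold,
    suppression_profile = suppression,
    context_multipliers = neutral_context(),
    symmetric = symmetric
  )
}

## exact paired reads (no errors) for one construct's amplicon, with G
## substitutions at the given 0-based arm-local adenosine positions per read
handmade_pairs <- function(construct, edited_per_read, arm = "upper",
                           read_length = 40L) {
  amp <- construct_amplicon(construct, arm)
  la <- nchar(amp)
  reads <- vapply(edited_per_read, function(pos) {
    chars <- strsplit(amp, "")[[1]]
    if (length(pos)) chars[pos + nchar("ACACTCTTTCCC") + 1L] <- "G"
    paste(chars, collapse = "")
  }, character(1))
  list(
    r1 = substr(reads, 1L, read_length),
    r2 = revcomp(substr(reads, la - read_length + 1L, la))
  )
}

## ---- independent oracles --------------------------------------------------

## brute-force per-position A/G tally straight off the read strings
oracle_tally <- function(reads, a_positions_amplicon) {
  vapply(a_positions_amplicon, function(p) {
    bases <- substring(reads, p, p)
    c(a = sum(bases == "A"), g = sum(bases == "G"))
  }, integer(2))
}

## local linear regression with tricube weights, computed longhand
oracle_loess <- function(x, y, span, xout = sort(unique(x))) {
  n <- length(x)
  q <- max(2L, floor(span * n))
  vapply(xout, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[q]
    w <- (1 - pmin(1, d / max(h, .Machine$double.eps))^3)^3
    keep <- w > 0
    fit <- stats::lm.wfit(cbind(1, x[keep] - x0), y[keep], w[keep])
    unname(fit$coefficients[1])
  }, numeric(1))
}

## naive innermost-first bracket matching (O(n^2)); 1-based partner or NA
oracle_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  n <- length(chars)
  state <- chars
  pair <- rep(NA_integer_, n)
  repeat {
    opens <- which(state == "(")
    if (!length(opens)) break
    matched <- FALSE
    for (i in opens) {
      j <- i + 1L
      while (j <= n && (state[j] == "." || state[j] == "x")) j <- j + 1L
      if (j <= n && state[j] == ")") {
        pair[i] <- j
        pair[j] <- i
        state[i] <- "x"
        state[j] <- "x"
        matched <- TRUE
        break
      }
    }
    if (!matched) stop("oracle: unbalanced structure")
  }
  if (any(state == ")")) stop("oracle: unbalanced structure")
  pair
}

## element labels from first principles via exhaustive search over pairs
oracle_labels <- function(db) {
  chars <- strsplit(db, "")[[1]]
  n <- length(chars)
  pair <- oracle_pairs(db)
  labels <- rep(NA_character_, n)
  labels[!is.na(pair)] <- "stem"
  open_pairs <- which(chars == "(")
  enclosing <- function(i) {
    cands <- open_pairs[open_pairs < i & pair[open_pairs] > i]
    if (!length(cands)) {
      return(NA_integer_)
    }
    cands[which.min(pair[cands] - cands)]
  }
  direct_children <- function(a) {
    b <- pair[a]
    inside <- open_pairs[open_pairs > a & open_pairs < b]
    inside[vapply(inside, function(c_) {
      !any(inside != c_ & inside < c_ & pair[inside] > pair[c_])
    }, logical(1))]
  }
  for (i in which(is.na(pair))) {
    a <- enclosing(i)
    if (is.na(a)) {
      labels[i] <- "exterior"
      next
    }
    b <- pair[a]
    kids <- direct_children(a)
    if (length(kids) == 0L) {
      labels[i] <- "hairpin_loop"
    } else if (length(kids) >= 2L) {
      labels[i] <- "multiloop"
    } else {
      left <- any(is.na(pair[(a + 1L):(kids[1] - 1L)])) &&
        kids[1] > a + 1L
      right <- any(is.na(pair[(pair[kids[1]] + 1L):(b - 1L)])) &&
        b > pair[kids[1]] + 1L
      labels[i] <- if (isTRUE(left) && isTRUE(right)) "internal_loop" else "bulge"
    }
  }
  labels
}

## random balanced non-crossing dot-bracket string
random_dotbracket <- function(max_len = 60L) {
  n_body <- sample(10:(max_len - 4L), 1)
  chars <- character(0)
  depth <- 0L
  for (i in seq_len(n_body)) {
    roll <- stats::runif(1)
    if (roll < 0.35) {
      chars <- c(chars, "(")
      depth <- depth + 1L
    } else if (roll < 0.65 && depth > 0L) {
      chars <- c(chars, ")")
      depth <- depth - 1L
    } else {
      chars <- c(chars, ".")
    }
  }
  chars <- c(chars, rep(")", depth))
  paste(chars, collapse = "")
}
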