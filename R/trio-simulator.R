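#' Generate a random ancestral genome
#'
#' Uniform i.i.d. A/C/G/T string standing in, at desk scale, for a reference
#' chromosome.
#'
#' @param length genome length in bases (>= 1000).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return a single DNA string.
#' @export
generate_genome <- function(length, seed = 1L) {
  if (length < 1000L) stop("genome length must be at least 1000 bases")
  with_seed(substream_seed(seed, "genome"),
            paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = ""))
}

#' Simulate a diploid trio with inherited and de novo variants
#'
#' Implants a pool of inherited variants (SNPs and small insertions or
#' deletions) into two diploid parents, builds the child's haplotypes by
#' copying one haplotype of each parent (optionally with a crossover), and
#' injects de novo structural variants -- insertions, deletions and
#' inversions in as-equal-as-possible numbers -- into the child haplotypes.
#' All variants are placed without overlap on the ancestral coordinate
#' system, so each haplotype is the ancestral genome with its own variant
#' subset applied in a single pass, and haplotype-to-ancestral liftover is
#' exact outside variant intervals.
#'
#' @param genome ancestral genome string (see [generate_genome()]).
#' @param n_inherited number of inherited variants in the parental pool.
#' @param n_denovo number of de novo SVs on the child haplotypes.
#' @param sv_size_range length range (bases) for de novo SVs.
#' @param inherited_size_range length range for inherited indels (SNPs are
#'   always length 1).
#' @param recombination if `TRUE`, each child haplotype is a single-crossover
#'   mosaic of the two haplotypes of one parent; the default `FALSE` copies
#'   one parental haplotype verbatim, so de novo variants are the only source
#'   of child-specific sequence.
#' @param edge_margin fraction of the genome length kept variant-free at each
#'   end.  At desk scale (reads a substantial fraction of the genome length)
#'   positions near a sequence boundary are fully contained in few reads, an
#'   edge artifact that does not exist at chromosome scale; the margin keeps
#'   the truth set out of that zone.
#' @param seed integer seed.
#' @return an object of class `TrioSim`: list with `genome`, `haplotypes`
#'   (named character vector: `father_1/2`, `mother_1/2`, `child_1/2`),
#'   `variants` (truth table, 0-based `ref_pos`), `placements` (per carrier
#'   haplotype: 0-based half-open `hap_start`/`hap_end` intervals),
#'   `liftover` (identity-segment maps per haplotype) and `params`.
#' @export
make_trio <- function(genome, n_inherited = 20L, n_denovo = 20L,
                      sv_size_range = c(50L, 500L),
                      inherited_size_range = c(1L, 50L),
                      recombination = FALSE, edge_margin = 0.1, seed = 1L) {
  n <- nchar(genome)
  if (n < 1000L) stop("genome too short for trio simulation")
  with_seed(substream_seed(seed, "variants"), {
    vars <- sample_variants(genome, n_inherited, n_denovo, sv_size_range,
                            inherited_size_range, edge_margin)
    # inherited assignment: carrier parent and zygosity
    inh <- vars$origin != "de_novo"
    hap_sets <- list(father_1 = integer(0), father_2 = integer(0),
                     mother_1 = integer(0), mother_2 = integer(0),
                     child_1 = integer(0), child_2 = integer(0))
    for (k in which(inh)) {
      parent <- sample(c("father", "mother"), 1L)
      vars$origin[k] <- paste0("inherited_", parent)
      haps <- if (stats::runif(1) < 0.5) 1:2 else sample(1:2, 1L)
      for (h in haps) {
        nm <- paste0(parent, "_", h)
        hap_sets[[nm]] <- c(hap_sets[[nm]], k)
      }
    }
    # child inherits one haplotype per parent
    for (side in c(1L, 2L)) {
      parent <- c("father", "mother")[side]
      chosen <- sample(1:2, 1L)
      inherited_set <- hap_sets[[paste0(parent, "_", chosen)]]
      if (recombination) {
        x <- sample.int(n, 1L) - 1L # crossover point, ancestral coords
        other <- hap_sets[[paste0(parent, "_", 3L - chosen)]]
        inherited_set <- c(inherited_set[vars$ref_pos[inherited_set] < x],
                           other[vars$ref_pos[other] >= x])
      }
      hap_sets[[paste0("child_", side)]] <- sort(inherited_set)
    }
    # de novo variants land on one child haplotype each
    for (k in which(vars$origin == "de_novo")) {
      nm <- paste0("child_", sample(1:2, 1L))
      hap_sets[[nm]] <- sort(c(hap_sets[[nm]], k))
    }
    haplotypes <- character(0)
    placements <- list()
    liftover <- list()
    for (nm in names(hap_sets)) {
      ap <- apply_variants(genome, vars[hap_sets[[nm]], , drop = FALSE])
      haplotypes[nm] <- ap$seq
      liftover[[nm]] <- ap$segments
      if (nrow(ap$placements)) {
        ap$placements$haplotype <- nm
        placements[[nm]] <- ap$placements
      }
    }
    placements <- if (length(placements)) {
      do.call(rbind, c(unname(placements), list(make.row.names = FALSE)))
    } else {
      data.frame(variant_id = character(0), kind = character(0),
                 origin = character(0), hap_start = integer(0),
                 hap_end = integer(0), haplotype = character(0),
                 stringsAsFactors = FALSE)
    }
    out <- list(genome = genome, haplotypes = haplotypes, variants = vars,
                placements = placements, liftover = liftover,
                params = list(n_inherited = n_inherited, n_denovo = n_denovo,
                              sv_size_range = sv_size_range,
                              inherited_size_range = inherited_size_range,
                              recombination = recombination, seed = seed))
    class(out) <- "TrioSim"
    out
  })
}

#' @export
print.TrioSim <- function(x, ...) {
  cat("TrioSim:", nchar(x$genome), "bp ancestral genome;",
      sum(x$variants$origin != "de_novo"), "inherited variants,",
      sum(x$variants$origin == "de_novo"), "de novo SVs\n")
  invisible(x)
}

# Sample variant kinds, sizes, alt alleles and non-overlapping placements.
sample_variants <- function(genome, n_inherited, n_denovo, sv_size_range,
                            inherited_size_range, edge_margin = 0.1) {
  n <- nchar(genome)
  kind <- character(0); len <- integer(0); origin <- character(0)
  if (n_inherited > 0L) {
    k <- sample(c("SNP", "insertion", "deletion"), n_inherited, replace = TRUE)
    l <- ifelse(k == "SNP", 1L,
                sample(inherited_size_range[1]:inherited_size_range[2],
                       n_inherited, replace = TRUE))
    kind <- c(kind, k); len <- c(len, as.integer(l))
    origin <- c(origin, rep("inherited", n_inherited))
  }
  if (n_denovo > 0L) {
    # equally divided between insertions, deletions and inversions
    k <- rep(c("insertion", "deletion", "inversion"), length.out = n_denovo)
    l <- sample(sv_size_range[1]:sv_size_range[2], n_denovo, replace = TRUE)
    kind <- c(kind, k); len <- c(len, as.integer(l))
    origin <- c(origin, rep("de_novo", n_denovo))
  }
  m <- length(kind)
  if (m == 0L) stop("no variants requested")
  occ <- ifelse(kind == "insertion", 1L, len) # bases consumed on the genome
  buffer <- 2L
  # keep variants away from the genome ends: at desk scale, positions within
  # roughly one read length of a boundary are contained in few reads, an
  # artifact absent at chromosome scale
  margin <- as.integer(ceiling(edge_margin * n))
  lo <- margin; hi <- n - margin
  pos <- integer(m)
  taken_start <- integer(0); taken_end <- integer(0)
  for (k in seq_len(m)) {
    placed <- FALSE
    span <- hi - lo - occ[k] - 2L * buffer
    if (span < 1L)
      stop("could not place variants without overlap; ",
           "reduce counts or sizes relative to the genome length")
    for (try in seq_len(1000L)) {
      p <- lo + sample.int(span, 1L) + buffer
      s <- p - buffer; e <- p + occ[k] + buffer
      if (!any(taken_start < e & s < taken_end)) {
        pos[k] <- p
        taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place variants without overlap; ",
           "reduce counts or sizes relative to the genome length")
  }
  # alt alleles fixed here, once per variant, so every carrier haplotype
  # (parent and child alike) applies the identical change
  alt <- rep(NA_character_, m)
  for (k in seq_len(m)) {
    if (kind[k] == "SNP") {
      ref_base <- substr(genome, pos[k] + 1L, pos[k] + 1L)
      alt[k] <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1L)
    } else if (kind[k] == "insertion") {
      alt[k] <- paste(sample(c("A", "C", "G", "T"), len[k], replace = TRUE),
                      collapse = "")
    }
  }
  vars <- data.frame(variant_id = sprintf("var%03d", seq_len(m)),
                     kind = kind, origin = origin, ref_pos = pos,
                     length = len, alt = alt, stringsAsFactors = FALSE)
  vars <- vars[order(vars$ref_pos), , drop = FALSE]
  rownames(vars) <- NULL
  vars
}

# Apply a sorted, non-overlapping variant subset to the ancestral genome.
# Returns the haplotype string, identity segments (hap <-> ref liftover) and
# the 0-based half-open haplotype interval of every applied variant
# (hap_start == hap_end for deletions: the junction point).
apply_variants <- function(genome, vars) {
  vars <- vars[order(vars$ref_pos), , drop = FALSE]
  pieces <- character(0)
  seg <- list(); plc <- list()
  cur_ref <- 0L; cur_hap <- 0L
  emit_identity <- function(upto) {
    if (upto > cur_ref) {
      pieces[[length(pieces) + 1L]] <<- substr(genome, cur_ref + 1L, upto)
      seg[[length(seg) + 1L]] <<- c(hap_start = cur_hap, ref_start = cur_ref,
                                    length = upto - cur_ref)
      cur_hap <<- cur_hap + (upto - cur_ref)
      cur_ref <<- upto
    }
  }
  for (k in seq_len(nrow(vars))) {
    v <- vars[k, ]
    emit_identity(v$ref_pos)
    hs <- cur_hap
    if (v$kind == "SNP") {
      pieces[[length(pieces) + 1L]] <- v$alt
      cur_ref <- cur_ref + 1L; cur_hap <- cur_hap + 1L
    } else if (v$kind == "insertion") {
      pieces[[length(pieces) + 1L]] <- v$alt
      cur_hap <- cur_hap + v$length
    } else if (v$kind == "deletion") {
      cur_ref <- cur_ref + v$length
    } else if (v$kind == "inversion") {
      segment <- substr(genome, v$ref_pos + 1L, v$ref_pos + v$length)
      pieces[[length(pieces) + 1L]] <- rc(segment)
      cur_ref <- cur_ref + v$length; cur_hap <- cur_hap + v$length
    } else stop("unknown variant kind: ", v$kind)
    plc[[length(plc) + 1L]] <- data.frame(
      variant_id = v$variant_id, kind = v$kind, origin = v$origin,
      hap_start = hs, hap_end = cur_hap, stringsAsFactors = FALSE)
  }
  emit_identity(nchar(genome))
  segments <- as.data.frame(do.call(rbind, seg))
  placements <- if (length(plc)) {
    do.call(rbind, c(plc, list(make.row.names = FALSE)))
  } else {
    data.frame(variant_id = character(0), kind = character(0),
               origin = character(0), hap_start = integer(0),
               hap_end = integer(0), stringsAsFactors = FALSE)
  }
  list(seq = paste(unlist(pieces), collapse = ""), segments = segments,
       placements = placements)
}

#' Lift haplotype coordinates to ancestral coordinates (and back)
#'
#' Exact on identity segments (outside variant intervals); positions falling
#' inside a variant's haplotype interval return `NA`.
#'
#' @param trio a [TrioSim][make_trio].
#' @param haplotype haplotype name, e.g. `"child_1"`.
#' @param pos vector of 0-based positions.
#' @return vector of 0-based positions on the other coordinate system (`NA`
#'   where the liftover is undefined).
#' @export
hap_to_ref <- function(trio, haplotype, pos) {
  seg <- trio$liftover[[haplotype]]
  if (is.null(seg)) stop("unknown haplotype: ", haplotype)
  vapply(pos, function(p) {
    hit <- which(seg$hap_start <= p & p < seg$hap_start + seg$length)
    if (!length(hit)) return(NA_integer_)
    as.integer(seg$ref_start[hit[1]] + (p - seg$hap_start[hit[1]]))
  }, integer(1))
}

#' @rdname hap_to_ref
#' @export
ref_to_hap <- function(trio, haplotype, pos) {
  seg <- trio$liftover[[haplotype]]
  if (is.null(seg)) stop("unknown haplotype: ", haplotype)
  vapply(pos, function(p) {
    hit <- which(seg$ref_start <= p & p < seg$ref_start + seg$length)
    if (!length(hit)) return(NA_integer_)
    as.integer(seg$hap_start[hit[1]] + (p - seg$ref_start[hit[1]]))
  }, integer(1))
}

#' Simulate long reads from haplotypes
#'
#' Draws reads with uniform start positions and truncated-normal lengths from
#' each haplotype until the requested per-haplotype mean coverage is reached.
#' Strands are equiprobable; source coordinates are recorded before optional
#' error injection (substitutions, insertions and deletions mixed 6:2:2 at
#' the given per-base rate).  When a haplotype is shorter than five mean read
#' lengths the length model is scaled down proportionally.
#'
#' @param haplotypes named character vector of haplotype sequences.
#' @param coverage target mean coverage per haplotype (> 0).
#' @param read_length named numeric vector `c(mean, sd, min)` in bases;
#'   defaults emulate HiFi-scale reads (10 kb +- 2 kb, >= 1 kb).
#' @param error_rate per-base error probability in `[0, 0.05]`; 0 gives
#'   reads that are exact haplotype slices (up to reverse complement).
#' @param seed integer seed.
#' @param prefix read-id prefix (typically the sample name).
#' @return data.frame: `read_id`, `haplotype`, `hap_begin`, `hap_end`
#'   (0-based half-open, pre-error), `strand`, `errors_injected`, `sequence`.
#' @export
simulate_reads <- function(haplotypes, coverage,
                           read_length = c(mean = 10000, sd = 2000, min = 1000),
                           error_rate = 0, seed = 1L, prefix = "read") {
  if (coverage <= 0) stop("coverage must be positive")
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must be in [0, 0.05]")
  if (is.null(names(haplotypes)))
    names(haplotypes) <- paste0("hap_", seq_along(haplotypes))
  with_seed(substream_seed(seed, "reads"), {
    out <- list()
    for (nm in names(haplotypes)) {
      hap <- haplotypes[[nm]]
      hl <- nchar(hap)
      rl <- read_length
      if (hl < 5 * rl[["mean"]]) rl <- rl * (hl / (5 * rl[["mean"]]))
      target <- coverage * hl
      drawn <- 0; k <- 0L
      while (drawn < target) {
        len <- min(hl, max(round(rl[["min"]]),
                           round(stats::rnorm(1, rl[["mean"]], rl[["sd"]]))))
        # boundary-clipped sampling: raw starts range over [-(len-1), hl-1]
        # so coverage is uniform up to the sequence ends (reads overhanging a
        # boundary are clipped); unclipped simulators leave the first and
        # last read-length of a short haplotype underrepresented
        raw <- sample.int(hl + len - 1L, 1L) - len
        start <- max(0L, raw)
        end <- min(hl, raw + len)
        len <- end - start
        if (len < min(100L, hl)) next # unusably short clip
        k <- k + 1L
        strand <- sample(c("+", "-"), 1L)
        s <- substr(hap, start + 1L, start + len)
        if (strand == "-") s <- rc(s)
        nerr <- 0L
        if (error_rate > 0) {
          err <- inject_errors(s, error_rate)
          s <- err$seq; nerr <- err$n
        }
        out[[length(out) + 1L]] <- data.frame(
          read_id = sprintf("%s_%s_r%05d", prefix, nm, k),
          haplotype = nm, hap_begin = start, hap_end = start + len,
          strand = strand, errors_injected = nerr, sequence = s,
          stringsAsFactors = FALSE)
        drawn <- drawn + len
      }
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

# Inject substitutions/insertions/deletions (6:2:2) at the given per-base
# probability; returns the mutated sequence and the number of events.
inject_errors <- function(s, rate) {
  n <- nchar(s)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(list(seq = s, n = 0L))
  pos <- sort(sample.int(n, k))
  type <- sample(c("sub", "ins", "del"), k, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (t in seq_len(k)) {
    p <- pos[t]
    if (type[t] == "sub") {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    } else if (type[t] == "ins") {
      ch[p] <- paste0(sample(c("A", "C", "G", "T"), 1L), ch[p])
    } else {
      ch[p] <- ""
    }
  }
  list(seq = paste(ch, collapse = ""), n = k)
}

#' Reads for one trio sample
#'
#' Convenience wrapper drawing reads from both haplotypes of one sample of a
#' [TrioSim][make_trio].
#'
#' @param trio a `TrioSim`.
#' @param sample one of `"father"`, `"mother"`, `"child"`.
#' @inheritParams simulate_reads
#' @return as [simulate_reads()].
#' @export
trio_reads <- function(trio, sample = c("father", "mother", "child"),
                       coverage,
                       read_length = c(mean = 10000, sd = 2000, min = 1000),
                       error_rate = 0, seed = 1L) {
  sample <- match.arg(sample)
  haps <- trio$haplotypes[paste0(sample, "_", 1:2)]
  simulate_reads(haps, coverage, read_length = read_length,
                 error_rate = error_rate,
                 seed = seed + match(sample, c("father", "mother", "child")),
                 prefix = sample)
}

# Lift emission intervals (0-based half-open on the read) to haplotype
# coordinates.  Expects `emissions` joined against the read table rows.
lift_emissions <- function(emissions, reads) {
  hit <- match(emissions$target_id, reads$read_id)
  if (anyNA(hit)) stop("emission references unknown read: ",
                       emissions$target_id[which(is.na(hit))[1]])
  rl <- reads$hap_end[hit] - reads$hap_begin[hit]
  begin <- pmin(emissions$begin, rl)
  end <- pmin(emissions$end, rl)
  plus <- reads$strand[hit] == "+"
  hs <- ifelse(plus, reads$hap_begin[hit] + begin,
               reads$hap_begin[hit] + (rl - end))
  he <- ifelse(plus, reads$hap_begin[hit] + end,
               reads$hap_begin[hit] + (rl - begin))
  data.frame(haplotype = reads$haplotype[hit], hap_begin = as.integer(hs),
             hap_end = as.integer(he), stringsAsFactors = FALSE)
}

#' Truth variants overlapped by one emission
#'
#' Lifts an emission's read interval to haplotype coordinates and returns the
#' truth variants whose haplotype interval it covers, breakpoints inclusive:
#' an emission `[hs, he)` covers a variant placed at `[vs, ve)` iff
#' `hs <= ve` and `he >= vs` (for a deletion, `vs == ve` is the junction
#' point, so the emission must touch a base adjacent to the junction).
#'
#' @param emission one emission row (from [ping_pong_exact()] etc.) whose
#'   `target_id` names `read`.
#' @param read the matching row of a [simulate_reads()] table.
#' @param trio the [TrioSim][make_trio] the read was drawn from.
#' @return the overlapped rows of `trio$placements` (zero rows if none).
#' @export
variant_overlap <- function(emission, read, trio) {
  if (!identical(as.character(emission$target_id),
                 as.character(read$read_id)))
    stop("emission/read mismatch: emission targets ", emission$target_id,
         " but read is ", read$read_id)
  lifted <- lift_emissions(emission, read)
  plc <- trio$placements
  hit <- plc$haplotype == lifted$haplotype &
    lifted$hap_begin <= plc$hap_end & lifted$hap_end >= plc$hap_start
  plc[hit, , drop = FALSE]
}
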