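# Elastic-network construction: hydrogen-bond springs, surface-
# accessibility springs, their merged SAHBNET form, and the ELNEDYN
# comparator, plus statistics, comparison and parameter sweeps.

#' Network construction parameters
#'
#' @param sa_c relative solvent-accessibility cutoff (%): residues below
#'   it are "buried" and nucleate surface springs. Default 30.
#' @param r_c distance cutoff in nm for surface springs. Default 0.9 for
#'   BB networks; 0.5 is the calibrated choice for SC networks.
#' @param k_spring harmonic force constant, kJ mol^-1 nm^-2. Default 1000.
#' @param mode `"BB"` (springs between backbone beads) or `"SC"` (springs
#'   between side-chain beads).
#' @param min_sep_sa minimum sequence separation (chain-ordinal |i-j|) for
#'   surface springs; default 5 ("separated by five positions").
#' @param min_sep_eln minimum separation for ELNEDYN springs; default 3
#'   (i,i+1 and i,i+2 are covered by explicit bonded terms).
#' @return list of class `network_params`.
#' @export
network_params <- function(sa_c = 30, r_c = 0.9, k_spring = 1000,
                           mode = c("BB", "SC"), min_sep_sa = 5,
                           min_sep_eln = 3) {
  mode <- match.arg(mode)
  if (r_c <= 0) stop("r_c must be positive")
  if (k_spring <= 0) stop("k_spring must be positive")
  if (sa_c < 0) stop("sa_c must be non-negative")
  out <- list(sa_c = sa_c, r_c = r_c, k_spring = k_spring, mode = mode,
              min_sep_sa = min_sep_sa, min_sep_eln = min_sep_eln)
  class(out) <- "network_params"
  out
}

empty_springs <- function() {
  data.frame(i = integer(0), j = integer(0), b0 = numeric(0),
             k = numeric(0), origin = character(0),
             stringsAsFactors = FALSE)
}

spring_row <- function(i, j, b0, k, origin) {
  data.frame(i = pmin(i, j), j = pmax(i, j), b0 = b0, k = k,
             origin = origin, stringsAsFactors = FALSE)
}

bead_xyz <- function(model) as.matrix(model$beads[, c("x", "y", "z")])

#' Build hydrogen-bond springs
#'
#' One spring per unique undirected hydrogen-bonded residue pair, between
#' the two residues' backbone beads, with rest length equal to the bead
#' distance in the reference structure.
#'
#' @param model a `cg_model`.
#' @param hbonds an `hbond_list`, `stride_record`, or donor/acceptor
#'   data.frame (res_uid terms).
#' @param k force constant, kJ mol^-1 nm^-2.
#' @return springs data.frame (`i`, `j`, `b0`, `k`, `origin = "hbond"`).
#' @export
build_hbond_springs <- function(model, hbonds, k = 1000) {
  pairs <- hbond_pairs(hbonds)
  if (nrow(pairs) == 0) return(empty_springs())
  b <- model$beads
  bb <- b[b$kind == "BB", ]
  bi <- bb$index[match(pairs[, 1], bb$res_uid)]
  bj <- bb$index[match(pairs[, 2], bb$res_uid)]
  if (any(is.na(bi)) || any(is.na(bj))) {
    stop("hydrogen-bonded residue with no backbone bead in the model")
  }
  xyz <- bead_xyz(model)
  b0 <- sqrt(rowSums((xyz[bi, , drop = FALSE] -
                        xyz[bj, , drop = FALSE])^2))
  unique(spring_row(bi, bj, b0, k, "hbond"))
}

#' Build surface-accessibility springs
#'
#' Every residue whose relative accessibility is below `sa_c` ("buried")
#' has its bead(s) of the network's kind linked to all other residues'
#' beads of the same kind that lie within `r_c` in the reference
#' structure and are at least `min_sep_sa` positions away along the
#' chain. Partner residues need not themselves be buried; pairs on
#' different chains always satisfy the separation filter.
#'
#' @param model a `cg_model`.
#' @param rel_sa a `sasa_result` with relative values filled (from
#'   [relative_sasa()]), or a named numeric of relative SA (%) keyed by
#'   `res_uid`.
#' @param params a [network_params()] object.
#' @return springs data.frame (`origin = "sa"`), unique unordered pairs.
#' @export
build_sa_springs <- function(model, rel_sa, params = network_params()) {
  rel <- if (inherits(rel_sa, "sasa_result")) {
    if (is.null(rel_sa$residue_rel)) {
      stop("sasa_result lacks relative values; run relative_sasa() first")
    }
    rel_sa$residue_rel
  } else rel_sa
  b <- model$beads
  kind <- params$mode
  cand <- b[b$kind == kind, ]
  if (nrow(cand) == 0) return(empty_springs())

  rel_of_bead <- rel[as.character(cand$res_uid)]
  buried_res <- unique(cand$res_uid[!is.na(rel_of_bead) &
                                      rel_of_bead < params$sa_c])
  if (length(buried_res) == 0) return(empty_springs())

  xyz <- as.matrix(cand[, c("x", "y", "z")])
  n <- nrow(cand)
  out <- list()
  for (u in buried_res) {
    src <- which(cand$res_uid == u)
    for (s in src) {
      d <- sqrt(rowSums(sweep(xyz, 2, xyz[s, ], "-")^2))
      sep_ok <- cand$chain != cand$chain[s] |
        abs(cand$res_ord - cand$res_ord[s]) >= params$min_sep_sa
      hit <- which(d < params$r_c & sep_ok & seq_len(n) != s)
      if (length(hit) > 0) {
        out[[length(out) + 1]] <- spring_row(
          cand$index[s], cand$index[hit], d[hit], params$k_spring, "sa")
      }
    }
  }
  if (length(out) == 0) return(empty_springs())
  sp <- do.call(rbind, out)
  sp[!duplicated(sp[, c("i", "j")]), , drop = FALSE]
}

#' Build ELNEDYN comparator springs
#'
#' All backbone-bead pairs closer than `r_c` in the reference structure
#' and at least `min_sep` positions apart in sequence get a spring.
#'
#' @param model a `cg_model`; conventionally built with `bb_mode = "ca"`
#'   (ELNEDYN places backbone beads on the CA).
#' @param r_c distance cutoff, nm (default 0.9).
#' @param k force constant, kJ mol^-1 nm^-2 (default 500).
#' @param min_sep minimum chain-ordinal separation (default 3).
#' @return springs data.frame (`origin = "elnedyn"`).
#' @export
build_elnedyn_springs <- function(model, r_c = 0.9, k = 500, min_sep = 3) {
  b <- model$beads
  bb <- b[b$kind == "BB", ]
  n <- nrow(bb)
  if (n < 2) return(empty_springs())
  xyz <- as.matrix(bb[, c("x", "y", "z")])
  out <- list()
  for (s in seq_len(n - 1)) {
    rest <- (s + 1):n
    d <- sqrt(rowSums(sweep(xyz[rest, , drop = FALSE], 2, xyz[s, ], "-")^2))
    sep_ok <- bb$chain[rest] != bb$chain[s] |
      abs(bb$res_ord[rest] - bb$res_ord[s]) >= min_sep
    hit <- rest[d < r_c & sep_ok]
    if (length(hit) > 0) {
      out[[length(out) + 1]] <- spring_row(
        bb$index[s], bb$index[hit],
        d[which(d < r_c & sep_ok)], k, "elnedyn")
    }
  }
  if (length(out) == 0) return(empty_springs())
  do.call(rbind, out)
}

#' Assemble an elastic-network object
#'
#' @param springs springs data.frame (`i`, `j`, `b0`, `k`, `origin`).
#' @param params the [network_params()] used (or NULL).
#' @param model the `cg_model` the springs index into.
#' @param buried res_uids of buried residues (surface networks).
#' @return object of class `elastic_network` with per-origin provenance
#'   counts.
#' @export
elastic_network <- function(springs, params = NULL, model = NULL,
                            buried = integer(0)) {
  if (nrow(springs) > 0) {
    if (any(springs$i == springs$j)) stop("self-springs are not allowed")
    if (anyDuplicated(springs[, c("i", "j")]) > 0) {
      stop("duplicate spring pairs")
    }
  }
  counts <- table(factor(springs$origin,
                         levels = c("hbond", "sa", "elnedyn", "unknown")))
  out <- list(springs = springs, params = params, model = model,
              buried = buried, origin_counts = as.list(counts))
  class(out) <- "elastic_network"
  out
}

#' @export
print.elastic_network <- function(x, ...) {
  oc <- unlist(x$origin_counts)
  cat("elastic_network:", nrow(x$springs), "springs (",
      paste(names(oc)[oc > 0], oc[oc > 0], collapse = ", "), ")\n")
  invisible(x)
}

#' Build the merged SAHBNET network from a structure
#'
#' Full pipeline: solvent accessibility (local engine or a Stride
#' report), relative-SA normalization, backbone hydrogen bonds (detected
#' or from Stride), MARTINI bead mapping, hydrogen-bond springs plus
#' surface springs, merged with hydrogen-bond priority on duplicate bead
#' pairs (a doubled harmonic would double the effective force constant).
#'
#' @param structure a [structure3d] object.
#' @param params a [network_params()] object; `mode` selects BB or SC
#'   surface springs (hydrogen-bond springs always join backbone beads).
#' @param hbond_source `"detect"` (local energy criterion) or `"stride"`.
#' @param stride a `stride_record` (required when any source is
#'   `"stride"`); its SA values also replace the local engine's.
#' @param bb_mode backbone bead placement for the CG map (default `"com"`).
#' @return an `elastic_network` with the `cg_model` attached.
#' @export
build_sahbnet <- function(structure, params = network_params(),
                          hbond_source = c("detect", "stride"),
                          stride = NULL, bb_mode = "com") {
  hbond_source <- match.arg(hbond_source)
  if (hbond_source == "stride" && is.null(stride)) {
    stop("hbond_source = 'stride' requires a stride_record")
  }
  model <- map_structure(structure, bb_mode = bb_mode)

  rel <- if (!is.null(stride)) {
    relative_sasa(stride, residues = structure$residues)
  } else {
    relative_sasa(shrake_rupley(structure))$residue_rel
  }
  hb <- if (hbond_source == "stride") stride else {
    detect_backbone_hbonds(structure)
  }

  sp_hb <- build_hbond_springs(model, hb, k = params$k_spring)
  sp_sa <- build_sa_springs(model, rel, params)

  if (nrow(sp_hb) > 0 && nrow(sp_sa) > 0) {
    key_hb <- paste(sp_hb$i, sp_hb$j)
    sp_sa <- sp_sa[!paste(sp_sa$i, sp_sa$j) %in% key_hb, , drop = FALSE]
  }
  buried <- unique(model$beads$res_uid[
    model$beads$kind == params$mode &
      !is.na(rel[as.character(model$beads$res_uid)]) &
      rel[as.character(model$beads$res_uid)] < params$sa_c])
  elastic_network(rbind(sp_hb, sp_sa), params = params, model = model,
                  buried = buried)
}

#' Build an ELNEDYN network from a structure
#'
#' Convenience wrapper: CA-mode bead mapping plus
#' [build_elnedyn_springs()].
#'
#' @inheritParams build_elnedyn_springs
#' @param structure a [structure3d] object.
#' @return an `elastic_network` with the CA-mode `cg_model` attached.
#' @export
build_elnedyn <- function(structure, r_c = 0.9, k = 500, min_sep = 3) {
  model <- map_structure(structure, bb_mode = "ca")
  sp <- build_elnedyn_springs(model, r_c = r_c, k = k, min_sep = min_sep)
  elastic_network(sp, params = network_params(r_c = r_c, k_spring = k,
                                              min_sep_eln = min_sep),
                  model = model)
}

#' Summary statistics of an elastic network
#'
#' @param net an `elastic_network`.
#' @return list: `n_springs`, per-origin counts, `n_buried`, `degree`
#'   (named per-bead spring count over all beads of the model, when a
#'   model is attached), `length_hist` (hist of b0, nm).
#' @export
network_stats <- function(net) {
  sp <- net$springs
  n_beads <- if (!is.null(net$model)) nrow(net$model$beads) else {
    if (nrow(sp) > 0) max(sp$i, sp$j) else 0
  }
  degree <- integer(n_beads)
  if (nrow(sp) > 0) {
    t1 <- table(factor(sp$i, levels = seq_len(n_beads)))
    t2 <- table(factor(sp$j, levels = seq_len(n_beads)))
    degree <- as.integer(t1 + t2)
  }
  names(degree) <- seq_len(n_beads)
  lh <- if (nrow(sp) > 0) {
    graphics::hist(sp$b0, breaks = seq(0, max(sp$b0) + 0.1, by = 0.1),
                   plot = FALSE)
  } else NULL
  list(
    n_springs = nrow(sp),
    n_hbond = sum(sp$origin == "hbond"),
    n_sa = sum(sp$origin == "sa"),
    n_elnedyn = sum(sp$origin == "elnedyn"),
    n_buried = length(net$buried),
    degree = degree,
    length_hist = lh
  )
}

#' Compare two elastic networks on the same bead set
#'
#' @param a,b `elastic_network` objects built on models with identical
#'   bead counts and residue assignment.
#' @return list: `n_shared`, `jaccard`, `only_a`, `only_b` (pair
#'   data.frames), `density_diff` (per-residue spring-count difference,
#'   a minus b, over BB+SC beads of each residue).
#' @export
compare_networks <- function(a, b) {
  if (is.null(a$model) || is.null(b$model)) {
    stop("both networks need an attached model")
  }
  ba <- a$model$beads
  bb <- b$model$beads
  if (nrow(ba) != nrow(bb) || !all(ba$res_uid == bb$res_uid) ||
      !all(ba$kind == bb$kind)) {
    stop("networks are built on different bead sets")
  }
  key_a <- paste(a$springs$i, a$springs$j)
  key_b <- paste(b$springs$i, b$springs$j)
  shared <- intersect(key_a, key_b)
  uni <- union(key_a, key_b)
  jac <- if (length(uni) == 0) 1 else length(shared) / length(uni)

  res_deg <- function(net) {
    d <- network_stats(net)$degree
    tapply(d, ba$res_uid, sum)
  }
  da <- res_deg(a)
  db <- res_deg(b)
  list(
    n_shared = length(shared),
    jaccard = jac,
    only_a = a$springs[!key_a %in% key_b, , drop = FALSE],
    only_b = b$springs[!key_b %in% key_a, , drop = FALSE],
    density_diff = da - db
  )
}

#' Sweep network parameters over a grid
#'
#' Builds one SAHBNET per combination of the supplied cutoff grids and
#' tabulates its statistics. Rows are ordered by (sa_c, r_c, k_spring)
#' with sa_c varying slowest.
#'
#' @param structure a [structure3d] object.
#' @param sa_c,r_c,k numeric grids (non-empty).
#' @param mode `"BB"` or `"SC"`.
#' @param hbond_source,stride passed to [build_sahbnet()].
#' @return data.frame: `sa_c`, `r_c`, `k_spring`, `n_springs`, `n_hbond`,
#'   `n_sa`, `n_buried`.
#' @export
sweep_parameters <- function(structure, sa_c = c(10, 30, 50),
                             r_c = c(0.4, 0.9), k = 1000,
                             mode = "BB", hbond_source = "detect",
                             stride = NULL) {
  if (length(sa_c) == 0 || length(r_c) == 0 || length(k) == 0) {
    stop("empty parameter grid")
  }
  grid <- expand.grid(k_spring = k, r_c = r_c, sa_c = sa_c,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("sa_c", "r_c", "k_spring")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- network_params(sa_c = grid$sa_c[i], r_c = grid$r_c[i],
                        k_spring = grid$k_spring[i], mode = mode)
    net <- build_sahbnet(structure, p, hbond_source = hbond_source,
                         stride = stride)
    st <- network_stats(net)
    cbind(grid[i, ], n_springs = st$n_springs, n_hbond = st$n_hbond,
          n_sa = st$n_sa, n_buried = st$n_buried)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a network as a delimited edge list
#'
#' @param net an `elastic_network`.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(
    net$springs[, c("i", "j", "b0", "k", "origin")], path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = c("bead_i", "bead_j", "b0_nm", "k", "origin"))
  invisible(path)
}
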