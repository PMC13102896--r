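#' Arterial network topology
#'
#' An arterial topology bundles the 1D vessel tree (segments with length,
#' proximal/distal radius and a body-location tag), the terminal nodes
#' where lumped peripheral beds attach, junction metadata (reference
#' nodal resistance), the heart attachment node, and named measurement
#' sites used for quantity-of-interest extraction.
#'
#' @param segments tibble with columns `id`, `prox_node`, `dist_node`,
#'   `length` (m), `radius_prox`, `radius_dist` (m), `body_location`
#'   (one of `r conditions body_locations()`).
#' @param terminals tibble with columns `node`, `r_total` (reference
#'   total bed resistance, Pa s/m^3), `bed` (`"systemic"` or
#'   `"coronary"`), `body_location`, and optionally `tau1` (the
#'   first-compartment RC time in s, overriding the reference default).
#' @param sites tibble with columns `site`, `segment`, `position`
#'   (relative position along the segment in `[0, 1]`).
#' @param heart_node node id where the aortic valve attaches.
#' @param r_node_ref reference nodal resistance (Pa s/m^3) applied at
#'   every interior junction; models pressure loss into neglected side
#'   branches.
#' @return an object of class `cvpd_topology`.
#' @export
arterial_topology <- function(segments, terminals, sites, heart_node,
                              r_node_ref = 1e6) {
  topo <- structure(
    list(segments = tibble::as_tibble(segments),
         terminals = tibble::as_tibble(terminals),
         sites = tibble::as_tibble(sites),
         heart_node = heart_node,
         r_node_ref = r_node_ref),
    class = "cvpd_topology")
  validate_topology(topo)
  topo
}

#' Recognised body-location tags
#' @export
body_locations <- function() {
  c("arms", "legs", "spine", "coronaries", "brain", "face", "trunk")
}

#' Canonical measurement-site names
#' @export
site_names <- function() {
  c("aortic_root", "carotid", "radial", "brachial", "femoral",
    "ankle", "aortic_distal")
}

validate_topology <- function(topo) {
  seg <- topo$segments
  stopifnot(all(seg$length > 0), all(seg$radius_prox > 0),
            all(seg$radius_dist > 0))
  if (!all(seg$body_location %in% body_locations())) {
    stop("unknown body location tag", call. = FALSE)
  }
  nodes <- unique(c(seg$prox_node, seg$dist_node))
  if (!topo$heart_node %in% nodes) stop("heart node not in topology")
  if (!all(topo$terminals$node %in% nodes)) {
    stop("terminal node not referenced by any segment", call. = FALSE)
  }
  if (!all(topo$sites$segment %in% seg$id)) {
    stop("measurement site references unknown segment", call. = FALSE)
  }
  if (!all(topo$sites$position >= 0 & topo$sites$position <= 1)) {
    stop("measurement-site position outside [0, 1]", call. = FALSE)
  }
  # connectivity: undirected reachability from the heart node
  reach <- topo$heart_node
  repeat {
    hit <- seg$prox_node %in% reach | seg$dist_node %in% reach
    new <- unique(c(seg$prox_node[hit], seg$dist_node[hit]))
    if (all(new %in% reach)) break
    reach <- unique(c(reach, new))
  }
  if (!all(nodes %in% reach)) stop("topology graph is not connected")
  # each terminal node must touch exactly one segment end and no bed is
  # attached to the heart node
  ends <- c(seg$prox_node, seg$dist_node)
  deg <- table(ends)
  term_deg <- deg[as.character(topo$terminals$node)]
  if (any(term_deg != 1)) stop("terminal nodes must be leaves")
  if (topo$heart_node %in% topo$terminals$node) {
    stop("heart node cannot carry a peripheral bed")
  }
  invisible(topo)
}

#' @export
print.cvpd_topology <- function(x, ...) {
  cat("<cvpd_topology> ", nrow(x$segments), " segments, ",
      nrow(x$terminals), " terminal beds, ",
      nrow(x$sites), " measurement sites\n", sep = "")
  invisible(x)
}

#' Reduced 21-segment arterial tree fixture
#'
#' A deliberately reduced arterial tree carrying all seven canonical
#' measurement sites and all body-location tags: the aortic trunk, one
#' carotid with internal (brain) and external (face) branches, a
#' brachial-radial-ulnar arm path, visceral and renal branches, both
#' iliacs with a femoral-tibial leg path, and one coronary branch.
#' Dimensions follow the conventions of the classic multi-branch 1D
#' arterial models. Users substitute their own (e.g. a full anatomical
#' tree) through the same topology file format.
#'
#' Terminal bed resistances split a total systemic resistance across
#' beds by nominal regional flow fractions.
#'
#' @param r_total total systemic peripheral resistance (Pa s/m^3) to
#'   distribute over the terminal beds.
#' @return a `cvpd_topology`.
#' @export
fixture_tree <- function(r_total = 1.15e8) {
  seg <- function(id, pn, dn, len, rp, rd, loc) {
    tibble::tibble(id = id, prox_node = pn, dist_node = dn, length = len,
                   radius_prox = rp, radius_dist = rd, body_location = loc)
  }
  segments <- dplyr::bind_rows(
    seg("asc_aorta",       "n0",  "n1",  0.040, 0.0180, 0.0174, "trunk"),
    seg("aortic_arch_a",   "n1",  "n2",  0.030, 0.0142, 0.0138, "trunk"),
    seg("aortic_arch_b",   "n2",  "n3",  0.040, 0.0133, 0.0129, "trunk"),
    seg("thoracic_aorta",  "n3",  "n4",  0.160, 0.0122, 0.0102, "spine"),
    seg("abdominal_aorta", "n4",  "n5",  0.150, 0.0096, 0.0076, "spine"),
    seg("brachiocephalic", "n1",  "n6",  0.035, 0.0060, 0.0058, "trunk"),
    seg("r_subclavian",    "n6",  "n7",  0.034, 0.0042, 0.0040, "arms"),
    seg("r_brachial",      "n7",  "n8",  0.220, 0.0038, 0.0032, "arms"),
    seg("r_radial",        "n8",  "n9",  0.235, 0.0020, 0.0018, "arms"),
    seg("r_ulnar",         "n8",  "n10", 0.240, 0.0021, 0.0019, "arms"),
    seg("l_carotid",       "n2",  "n11", 0.120, 0.0037, 0.0035, "trunk"),
    seg("int_carotid",     "n11", "n12", 0.120, 0.0025, 0.0020, "brain"),
    seg("ext_carotid",     "n11", "n13", 0.110, 0.0020, 0.0017, "face"),
    seg("l_subclavian",    "n3",  "n14", 0.120, 0.0042, 0.0035, "arms"),
    seg("l_coronary",      "n1",  "n15", 0.050, 0.0020, 0.0015, "coronaries"),
    seg("celiac",          "n4",  "n16", 0.020, 0.0035, 0.0030, "trunk"),
    seg("renal",           "n4",  "n17", 0.030, 0.0026, 0.0024, "trunk"),
    seg("r_common_iliac",  "n5",  "n18", 0.058, 0.0040, 0.0036, "legs"),
    seg("l_common_iliac",  "n5",  "n19", 0.058, 0.0040, 0.0036, "legs"),
    seg("r_femoral",       "n18", "n20", 0.440, 0.0027, 0.0024, "legs"),
    seg("r_ant_tibial",    "n20", "n21", 0.340, 0.0021, 0.0018, "legs")
  )
  # regional flow fractions; distal limb beds (radial, ulnar, ankle)
  # carry only the flow their single supplying vessel can sustain, the
  # remainder of each limb drains through the proximal limb bed
  frac <- c(n9 = 0.01, n10 = 0.015, n12 = 0.12, n13 = 0.03, n14 = 0.075,
            n15 = 0.04, n16 = 0.28, n17 = 0.22, n19 = 0.19, n21 = 0.02)
  loc <- c(n9 = "arms", n10 = "arms", n12 = "brain", n13 = "face",
           n14 = "arms", n15 = "coronaries", n16 = "trunk", n17 = "trunk",
           n19 = "legs", n21 = "legs")
  # first-compartment RC time [s]: central/visceral beds lump the
  # compliance of the truncated vasculature; distal limb beds stay
  # resistive at pulse frequencies (physiological amplification)
  tau1 <- c(n9 = 0.25, n10 = 0.25, n12 = 0.30, n13 = 0.10, n14 = 0.30,
            n15 = 0.15, n16 = 0.80, n17 = 0.80, n19 = 0.60, n21 = 0.25)
  terminals <- tibble::tibble(
    node = names(frac),
    r_total = r_total / unname(frac),
    bed = ifelse(names(frac) == "n15", "coronary", "systemic"),
    body_location = unname(loc),
    tau1 = unname(tau1))
  sites <- tibble::tibble(
    site = site_names(),
    segment = c("asc_aorta", "l_carotid", "r_radial", "r_brachial",
                "r_femoral", "r_ant_tibial", "abdominal_aorta"),
    position = c(0, 0.5, 1, 0.5, 0.1, 1, 1))
  arterial_topology(segments, terminals, sites, heart_node = "n0")
}

#' Centerline path length between two measurement sites
#'
#' Shortest path along the vessel centerlines between two named sites,
#' computed on the segment graph with segment lengths as edge weights
#' and partial lengths at the site positions.
#'
#' @param topology a `cvpd_topology`.
#' @param from,to site names present in `topology$sites`.
#' @return path length in m.
#' @export
path_length <- function(topology, from, to) {
  seg <- topology$segments
  s1 <- topology$sites[topology$sites$site == from, ]
  s2 <- topology$sites[topology$sites$site == to, ]
  if (nrow(s1) != 1 || nrow(s2) != 1) stop("unknown site name")
  nodes <- unique(c(seg$prox_node, seg$dist_node))
  dist_from <- function(node) {
    # Dijkstra over the (small) node graph
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[node] <- 0
    visited <- character(0)
    while (length(visited) < length(nodes)) {
      un <- setdiff(nodes, visited)
      u <- un[which.min(d[un])]
      if (!is.finite(d[u])) break
      visited <- c(visited, u)
      touch <- seg$prox_node == u | seg$dist_node == u
      for (k in which(touch)) {
        v <- if (seg$prox_node[k] == u) seg$dist_node[k] else seg$prox_node[k]
        if (d[u] + seg$length[k] < d[v]) d[v] <- d[u] + seg$length[k]
      }
    }
    d
  }
  k2 <- which(seg$id == s2$segment)
  # distance from any node to site 2 = min over its two endpoint routes
  to_site2 <- pmin(
    dist_from(seg$prox_node[k2]) + s2$position * seg$length[k2],
    dist_from(seg$dist_node[k2]) + (1 - s2$position) * seg$length[k2])
  k1 <- which(seg$id == s1$segment)
  if (k1 == k2) {
    return(abs(s1$position - s2$position) * seg$length[k1])
  }
  min(to_site2[seg$prox_node[k1]] + s1$position * seg$length[k1],
      to_site2[seg$dist_node[k1]] + (1 - s1$position) * seg$length[k1])
}

#' PWV measurement paths
#'
#' The four diagnostic pulse-wave-velocity paths used for the QOIs:
#' aortic (aortic root to distal aorta), carotid-femoral,
#' brachial-radial, and femoral-ankle.
#'
#' @param topology a `cvpd_topology`.
#' @return tibble with columns `pwv`, `from`, `to`, `path_length`.
#' @export
pwv_paths <- function(topology) {
  p <- tibble::tibble(
    pwv = c("pwv_ao", "pwv_cf", "pwv_br", "pwv_fa"),
    from = c("aortic_root", "carotid", "brachial", "femoral"),
    to = c("aortic_distal", "femoral", "radial", "ankle"))
  p$path_length <- purrr::map2_dbl(p$from, p$to,
                                   ~ path_length(topology, .x, .y))
  p
}

#' Read and write topology files
#'
#' Plain-text, tab-delimited topology format with one record per row and
#' a `record` discriminator column (`segment`, `terminal`, `site`,
#' `meta`). Files round-trip byte-stably: `write_topology()` of a
#' just-read topology reproduces the file.
#'
#' @param topology a `cvpd_topology`.
#' @param path file path.
#' @name topology_io
#' @export
write_topology <- function(topology, path) {
  num <- function(x) sprintf("%.10g", x)
  rows <- c(
    "record\tid\ta\tb\tx1\tx2\tx3\tx4",
    sprintf("meta\theart_node\t%s\t\t%s\t\t\t",
            topology$heart_node, num(topology$r_node_ref)),
    with(topology$segments,
         sprintf("segment\t%s\t%s\t%s\t%s\t%s\t%s\t%s", id, prox_node,
                 dist_node, num(length), num(radius_prox),
                 num(radius_dist), body_location)),
    with(topology$terminals,
         sprintf("terminal\t%s\t%s\t%s\t%s\t%s\t\t", node, bed,
                 body_location, num(r_total), num(tau1))),
    with(topology$sites,
         sprintf("site\t%s\t%s\t\t%s\t\t\t", site, segment, num(position)))
  )
  writeLines(rows, path)
  invisible(path)
}

#' @rdname topology_io
#' @export
read_topology <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  meta <- raw[raw$record == "meta" & raw$id == "heart_node", , drop = FALSE]
  segs <- raw[raw$record == "segment", , drop = FALSE]
  term <- raw[raw$record == "terminal", , drop = FALSE]
  sit <- raw[raw$record == "site", , drop = FALSE]
  arterial_topology(
    segments = tibble::tibble(
      id = segs$id, prox_node = segs$a, dist_node = segs$b,
      length = as.numeric(segs$x1), radius_prox = as.numeric(segs$x2),
      radius_dist = as.numeric(segs$x3), body_location = segs$x4),
    terminals = tibble::tibble(
      node = term$id, r_total = as.numeric(term$x1), bed = term$a,
      body_location = term$b, tau1 = as.numeric(term$x2)),
    sites = tibble::tibble(
      site = sit$id, segment = sit$a, position = as.numeric(sit$x1)),
    heart_node = meta$a,
    r_node_ref = as.numeric(meta$x1))
}
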