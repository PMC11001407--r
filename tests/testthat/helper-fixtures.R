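# Flat (non-hierarchical) rebuild of the 5-star diblock chain: the same
# 40-unit topology as build_star_chain(), constructed sub-unit by sub-unit.
build_star_chain_flat <- function() {
  w <- sk_world()
  gid <- add_unit(w, "GaussianPolymer", "s1d1A", tag = "pA")
  link_unit(w, "GaussianPolymer", "s1d1B.end1", "s1d1A.end2", tag = "pB")
  for (d in 2:4) {
    link_unit(w, "GaussianPolymer", sprintf("s1d%dA.end1", d), "s1d1A.end1",
              tag = "pA")
    link_unit(w, "GaussianPolymer", sprintf("s1d%dB.end1", d),
              sprintf("s1d%dA.end2", d), tag = "pB")
  }
  for (s in 2:5) {
    link_unit(w, "GaussianPolymer", sprintf("s%dd1B.end2", s),
              sprintf("s%dd3B.end2", s - 1), tag = "pB")
    link_unit(w, "GaussianPolymer", sprintf("s%dd1A.end2", s),
              sprintf("s%dd1B.end1", s), tag = "pA")
    for (d in 2:4) {
      link_unit(w, "GaussianPolymer", sprintf("s%dd%dA.end1", s, d),
                sprintf("s%dd1A.end1", s), tag = "pA")
      gid <- link_unit(w, "GaussianPolymer", sprintf("s%dd%dB.end1", s, d),
                       sprintf("s%dd%dA.end2", s, d), tag = "pB")
    }
  }
  wrap_structure(w, gid, "flatchain")
  list(world = w, name = "flatchain")
}
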