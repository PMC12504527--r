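#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// Connected-component labeling of a binary mask stored in R array order
// (first dimension fastest). dim has length 2 (ny, nx) or 3 (nz, ny, nx).
// connectivity: 4 or 8 (2D), 6 or 26 (3D). Final labels are renumbered by
// first occurrence in storage order, so label k's first pixel precedes
// label k+1's in the flattened array.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nd = dim.size();
  if (nd != 2 && nd != 3)
    stop("mask must be 2- or 3-dimensional");
  const int d0 = dim[0], d1 = dim[1], d2 = (nd == 3) ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  if (mask.size() != n) stop("mask length does not match dim");

  // offsets of already-visited neighbours (strictly earlier in storage order)
  std::vector<std::array<int,3>> offs;
  for (int k2 = -1; k2 <= 1; ++k2)
    for (int k1 = -1; k1 <= 1; ++k1)
      for (int k0 = -1; k0 <= 1; ++k0) {
        if (nd == 2 && k2 != 0) continue;
        if (k0 == 0 && k1 == 0 && k2 == 0) continue;
        // strictly prior in storage order (dim0 fastest, dim2 slowest)
        bool prior = (k2 < 0) || (k2 == 0 && k1 < 0) ||
                     (k2 == 0 && k1 == 0 && k0 < 0);
        if (!prior) continue;
        int manhattan = std::abs(k0) + std::abs(k1) + std::abs(k2);
        bool keep;
        if (nd == 2)
          keep = (connectivity == 8) || manhattan == 1;
        else
          keep = (connectivity == 26) || manhattan == 1;
        if (keep) offs.push_back({k0, k1, k2});
      }

  std::vector<int> provisional(n, 0);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0); // dummy so labels are 1-based

  for (int i2 = 0; i2 < d2; ++i2)
    for (int i1 = 0; i1 < d1; ++i1)
      for (int i0 = 0; i0 < d0; ++i0) {
        R_xlen_t idx = i0 + (R_xlen_t)d0 * (i1 + (R_xlen_t)d1 * i2);
        if (!mask[idx]) continue;
        int lab = 0;
        for (size_t o = 0; o < offs.size(); ++o) {
          int j0 = i0 + offs[o][0], j1 = i1 + offs[o][1], j2 = i2 + offs[o][2];
          if (j0 < 0 || j0 >= d0 || j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2)
            continue;
          R_xlen_t jdx = j0 + (R_xlen_t)d0 * (j1 + (R_xlen_t)d1 * j2);
          int nl = provisional[jdx];
          if (nl == 0) continue;
          if (lab == 0) lab = nl;
          else if (nl != lab) uf_union(parent, lab, nl);
        }
        if (lab == 0) {
          lab = (int)parent.size();
          parent.push_back(lab);
        }
        provisional[idx] = lab;
      }

  // renumber roots by first occurrence in storage order
  std::vector<int> newlab(parent.size(), 0);
  int next = 0;
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int p = provisional[i];
    if (p == 0) { out[i] = 0; continue; }
    int r = uf_find(parent, p);
    if (newlab[r] == 0) newlab[r] = ++next;
    out[i] = newlab[r];
  }
  out.attr("dim") = dim;
  out.attr("n_objects") = next;
  return out;
}
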