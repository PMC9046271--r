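#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Volumes arrive as R integer arrays with dim = (nz, ny, nx); R is
// column-major so the z index varies fastest.
static inline size_t vidx(int z, int y, int x, int nz, int ny) {
  return (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x);
}

// Foreground 26-neighbour count of p (center excluded).
static int n26_count(const int* v, int z, int y, int x, int nz, int ny) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dz && !dy && !dx) continue;
        n += v[vidx(z + dz, y + dy, x + dx, nz, ny)];
      }
  return n;
}

// Simple-point test for (26, 6) digital topology on the 3x3x3
// neighbourhood: deletion of p preserves topology iff
//  (a) the foreground of N26*(p) forms exactly one 26-connected component
//  (b) the background of N18(p) has exactly one 6-connected component
//      that is 6-adjacent to p.
static bool is_simple(const int* v, int z, int y, int x, int nz, int ny) {
  int nb[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        nb[(dz + 1) * 9 + (dy + 1) * 3 + (dx + 1)] =
          v[vidx(z + dz, y + dy, x + dx, nz, ny)];
  nb[13] = 0; // remove the center

  // (a) 26-connectivity flood fill over foreground neighbours
  int seen[27];
  std::memset(seen, 0, sizeof(seen));
  int stack[27], top = 0, comps = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    if (++comps > 1) return false;
    stack[top++] = i; seen[i] = 1;
    while (top) {
      int c = stack[--top];
      int cz = c / 9, cy = (c % 9) / 3, cx = c % 3;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int az = cz + dz, ay = cy + dy, ax = cx + dx;
            if (az < 0 || az > 2 || ay < 0 || ay > 2 || ax < 0 || ax > 2)
              continue;
            int a = az * 9 + ay * 3 + ax;
            if (a == 13 || seen[a] || !nb[a]) continue;
            seen[a] = 1; stack[top++] = a;
          }
    }
  }
  if (comps != 1) return false;

  // (b) 6-connectivity flood fill over background within N18, seeded at
  // the six face neighbours; exactly one such component may exist.
  std::memset(seen, 0, sizeof(seen));
  const int face[6] = {4, 10, 12, 14, 16, 22};
  comps = 0; top = 0;
  for (int f = 0; f < 6; ++f) {
    int i = face[f];
    if (nb[i] || seen[i]) continue;
    if (++comps > 1) return false;
    stack[top++] = i; seen[i] = 1;
    while (top) {
      int c = stack[--top];
      int cz = c / 9, cy = (c % 9) / 3, cx = c % 3;
      const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; ++k) {
        int az = cz + d6[k][0], ay = cy + d6[k][1], ax = cx + d6[k][2];
        if (az < 0 || az > 2 || ay < 0 || ay > 2 || ax < 0 || ax > 2) continue;
        // stay inside N18: exclude the center and the 8 corners
        int off = (az != 1) + (ay != 1) + (ax != 1);
        if (off == 0 || off == 3) continue;
        int a = az * 9 + ay * 3 + ax;
        if (seen[a] || nb[a]) continue;
        seen[a] = 1; stack[top++] = a;
      }
    }
  }
  return comps == 1;
}

//' @noRd
// [[Rcpp::export]]
IntegerVector thin_volume_cpp(IntegerVector vol, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector out = clone(vol);
  int* v = INTEGER(out);

  // six directional subiterations: U, D, N, S, E, W border points
  const int dir[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  std::vector<size_t> cand;
  std::vector<int> cz, cy, cx;

  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear(); cz.clear(); cy.clear(); cx.clear();
      // volume carries a 1-voxel zero border, so interior scan suffices
      for (int x = 1; x < nx - 1; ++x)
        for (int y = 1; y < ny - 1; ++y)
          for (int z = 1; z < nz - 1; ++z) {
            size_t i = vidx(z, y, x, nz, ny);
            if (!v[i]) continue;
            if (v[vidx(z + dir[d][0], y + dir[d][1], x + dir[d][2], nz, ny)])
              continue; // not a border point in this direction
            int nn = n26_count(v, z, y, x, nz, ny);
            if (nn <= 1) continue; // endpoint or isolated voxel: preserved
            if (!is_simple(v, z, y, x, nz, ny)) continue;
            cand.push_back(i); cz.push_back(z); cy.push_back(y); cx.push_back(x);
          }
      // sequential recheck: earlier deletions can make a candidate
      // non-simple, so each point is re-verified before removal
      for (size_t k = 0; k < cand.size(); ++k) {
        if (n26_count(v, cz[k], cy[k], cx[k], nz, ny) <= 1) continue;
        if (!is_simple(v, cz[k], cy[k], cx[k], nz, ny)) continue;
        v[cand[k]] = 0;
        changed = true;
      }
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector vol, IntegerVector dims,
                                   int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t n = (size_t)nz * ny * nx;
  const int* v = INTEGER(vol);
  IntegerVector lab(vol.size(), 0);
  int* L = INTEGER(lab);

  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!v[s] || L[s]) continue;
    ++next;
    L[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t c = stack.back(); stack.pop_back();
      int z = (int)(c % nz), y = (int)((c / nz) % ny), x = (int)(c / ((size_t)nz * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            if (connectivity == 6 && (std::abs(dz) + std::abs(dy) + std::abs(dx)) > 1)
              continue;
            int az = z + dz, ay = y + dy, ax = x + dx;
            if (az < 0 || az >= nz || ay < 0 || ay >= ny || ax < 0 || ax >= nx)
              continue;
            size_t a = vidx(az, ay, ax, nz, ny);
            if (!v[a] || L[a]) continue;
            L[a] = next;
            stack.push_back(a);
          }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = next;
  return lab;
}
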