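// Binary morphology helpers for the skin-mask chain: in-plane (per-slice)
// dilation/erosion with a disk, 6-connected 3D component labeling, and
// per-slice hole filling. Masks are [nz,ny,nx] 0/1 integer vectors.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector dilate_inplane_cpp(IntegerVector mask, IntegerVector dim, int r) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector out((long)nz * ny * nx);
  std::vector<std::pair<int,int>> disk;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      if (dy * dy + dx * dx <= r * r) disk.push_back({dy, dx});
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        long i = z + (long)nz * (y + (long)ny * x);
        if (!mask[i]) continue;
        for (auto& d : disk) {
          int yy = y + d.first, xx = x + d.second;
          if (yy >= 0 && yy < ny && xx >= 0 && xx < nx)
            out[z + (long)nz * (yy + (long)ny * xx)] = 1;
        }
      }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
List label_components_cpp(IntegerVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long N = (long)nz * ny * nx;
  IntegerVector lab(N);
  std::vector<long> sizes;
  int cur = 0;
  std::vector<long> stack;
  for (long s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    long size = 0;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      long i = stack.back(); stack.pop_back();
      ++size;
      int z = i % nz, y = (i / nz) % ny, x = i / ((long)nz * ny);
      const int dz[6] = {1,-1,0,0,0,0}, dy6[6] = {0,0,1,-1,0,0}, dx6[6] = {0,0,0,0,1,-1};
      for (int d = 0; d < 6; ++d) {
        int zz = z + dz[d], yy = y + dy6[d], xx = x + dx6[d];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        long j = zz + (long)nz * (yy + (long)ny * xx);
        if (mask[j] && !lab[j]) { lab[j] = cur; stack.push_back(j); }
      }
    }
    sizes.push_back(size);
  }
  lab.attr("dim") = dim;
  return List::create(_["labels"] = lab,
                      _["sizes"] = NumericVector(sizes.begin(), sizes.end()));
}

// Fill holes slice by slice: background connected to the slice border stays
// background, enclosed background becomes foreground.
// [[Rcpp::export]]
IntegerVector fill_holes_inplane_cpp(IntegerVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector out(clone(mask));
  std::vector<char> outside((long)ny * nx);
  std::vector<long> stack;
  for (int z = 0; z < nz; ++z) {
    std::fill(outside.begin(), outside.end(), 0);
    stack.clear();
    auto midx = [&](int y, int x) { return (long)z + (long)nz * (y + (long)ny * x); };
    auto sidx = [&](int y, int x) { return (long)y + (long)ny * x; };
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        if ((y == 0 || y == ny - 1 || x == 0 || x == nx - 1) &&
            !mask[midx(y, x)] && !outside[sidx(y, x)]) {
          outside[sidx(y, x)] = 1;
          stack.push_back(sidx(y, x));
        }
    while (!stack.empty()) {
      long i = stack.back(); stack.pop_back();
      int y = i % ny, x = i / ny;
      const int dy4[4] = {1,-1,0,0}, dx4[4] = {0,0,1,-1};
      for (int d = 0; d < 4; ++d) {
        int yy = y + dy4[d], xx = x + dx4[d];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        if (!mask[midx(yy, xx)] && !outside[sidx(yy, xx)]) {
          outside[sidx(yy, xx)] = 1;
          stack.push_back(sidx(yy, xx));
        }
      }
    }
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        if (!mask[midx(y, x)] && !outside[sidx(y, x)]) out[midx(y, x)] = 1;
  }
  return out;
}
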