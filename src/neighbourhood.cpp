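#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median over a cubic window of odd edge length w, centre voxel included,
// window truncated at the volume borders.  Median convention matches R's
// stats::median (mean of the two middle values for even counts).
// [[Rcpp::export(name = ".cppMedianFilter3")]]
NumericVector cppMedianFilter3(NumericVector vol, IntegerVector dims,
                               int w) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = (w - 1) / 2;
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve((size_t)w * w * w);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        buf.clear();
        const int x0 = std::max(0, x - r), x1 = std::min(nx - 1, x + r);
        const int y0 = std::max(0, y - r), y1 = std::min(ny - 1, y + r);
        const int z0 = std::max(0, z - r), z1 = std::min(nz - 1, z + r);
        for (int zz = z0; zz <= z1; ++zz)
          for (int yy = y0; yy <= y1; ++yy)
            for (int xx = x0; xx <= x1; ++xx)
              buf.push_back(vol[xx + nx * (yy + (R_xlen_t)ny * zz)]);
        const size_t n = buf.size();
        const size_t m = n / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (n % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + m);
          med = (med + lo) / 2.0;
        }
        out[x + nx * (y + (R_xlen_t)ny * z)] = med;
      }
    }
  }
  return out;
}

// Bowsher neighbour selection.  offsets: K x 3 integer matrix of candidate
// neighbour offsets, already ordered by (centre distance, lexicographic
// offset) — the scan order.  For every voxel the B candidates with the
// smallest |anat[j+k] - anat[j]| are kept; a stable sort over the presorted
// candidates realises the (distance, lexicographic) tie-break.  Candidates
// outside the volume are skipped; if fewer than B remain, all are kept.
// Returns an nvox x K 0/1 selection matrix.
// [[Rcpp::export(name = ".cppBowsherSelect")]]
IntegerMatrix cppBowsherSelect(NumericVector anat, IntegerVector dims,
                               IntegerMatrix offsets, int B) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int K = offsets.nrow();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerMatrix sel(nvox, K);
  std::vector<int> cand(K), pos(K);
  std::vector<double> diff(K);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t j = x + nx * (y + (R_xlen_t)ny * z);
        const double cv = anat[j];
        int m = 0;
        for (int k = 0; k < K; ++k) {
          const int xx = x + offsets(k, 0);
          const int yy = y + offsets(k, 1);
          const int zz = z + offsets(k, 2);
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
              zz < 0 || zz >= nz)
            continue;
          cand[m] = k;
          diff[m] = std::abs(anat[xx + nx * (yy + (R_xlen_t)ny * zz)] - cv);
          ++m;
        }
        const int keep = std::min(B, m);
        for (int k = 0; k < m; ++k) pos[k] = k;
        std::stable_sort(pos.begin(), pos.begin() + m,
          [&](int a, int b) { return diff[a] < diff[b]; });
        for (int k = 0; k < keep; ++k) sel(j, cand[pos[k]]) = 1;
      }
    }
  }
  return sel;
}
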