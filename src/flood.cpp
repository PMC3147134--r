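#include <Rcpp.h>
using namespace Rcpp;

// Connected component of a binary 3-D field containing a seed voxel.
// `member` is a logical vector in column-major (R array) order for a grid of
// dimensions `dims`; `seed` is a 1-based linear index. Connectivity is 6
// (faces) or 26 (faces + edges + corners). Returns the 1-based linear
// indices of the component, sorted ascending.
// [[Rcpp::export]]
IntegerVector flood_component(LogicalVector member, IntegerVector dims,
                              int seed, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (member.size() != n) stop("member length does not match dims");
  if (seed < 1 || seed > n) stop("seed index out of range");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  if (!member[seed - 1]) return IntegerVector(0);

  std::vector<signed char> state(n, 0);  // 0 = unseen, 1 = queued/visited
  std::vector<int> queue;
  queue.reserve(1024);
  queue.push_back(seed - 1);
  state[seed - 1] = 1;

  std::vector<int> out;
  out.reserve(1024);

  size_t head = 0;
  while (head < queue.size()) {
    const int idx = queue[head++];
    out.push_back(idx + 1);
    const int z = idx / (nx * ny);
    const int rem = idx - z * nx * ny;
    const int y = rem / nx;
    const int x = rem - y * nx;
    for (int dz = -1; dz <= 1; ++dz) {
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1)
            continue;
          const int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          const int nidx = xx + nx * (yy + (R_xlen_t)ny * zz);
          if (!state[nidx] && member[nidx]) {
            state[nidx] = 1;
            queue.push_back(nidx);
          }
        }
      }
    }
  }
  std::sort(out.begin(), out.end());
  return IntegerVector(out.begin(), out.end());
}
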