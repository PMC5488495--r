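#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

static inline int find_root(std::vector<int>& zpar, int p) {
  while (zpar[p] != p) {
    zpar[p] = zpar[zpar[p]];  // path halving
    p = zpar[p];
  }
  return p;
}

// Max-tree of a quantized 2-D image by union-find over pixels sorted in
// decreasing gray level (4-connectivity). Returns, per pixel, the canonical
// parent pointer after level canonicalization: pixels with the same canonical
// element belong to the same tree node (one node per connected component per
// distinct level at which it exists).
//
// img: integer matrix (row-major access via (r, c)); values >= 0.
// Returns 0-based `parent` (pixel index, column-major), `value`, and the
// processing order (decreasing value, stable).
// [[Rcpp::export]]
List maxtree_build(IntegerMatrix img) {
  const int H = img.nrow(), W = img.ncol(), N = H * W;
  std::vector<int> val(N);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) val[c * H + r] = img(r, c);

  std::vector<int> ord(N);
  std::iota(ord.begin(), ord.end(), 0);
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return val[a] > val[b]; });

  std::vector<int> parent(N, -1), zpar(N, -1);
  std::vector<char> done(N, 0);
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  for (int i = 0; i < N; ++i) {
    const int p = ord[i];
    parent[p] = p;
    zpar[p] = p;
    const int pr = p % H, pc = p / H;
    for (int k = 0; k < 4; ++k) {
      const int nr = pr + dr[k], nc = pc + dc[k];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      const int n = nc * H + nr;
      if (!done[n]) continue;
      const int rt = find_root(zpar, n);
      if (rt != p) {
        parent[rt] = p;
        zpar[rt] = p;
      }
    }
    done[p] = 1;
  }

  // Canonicalize in reverse processing order so that every pixel's parent
  // pointer reaches the level-representative (canonical) element directly.
  for (int i = N - 1; i >= 0; --i) {
    const int p = ord[i];
    const int q = parent[p];
    if (val[parent[q]] == val[q]) parent[p] = parent[q];
  }

  return List::create(_["parent"] = wrap(parent), _["value"] = wrap(val),
                      _["order"] = wrap(ord));
}
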