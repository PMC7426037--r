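#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Z/2 boundary-matrix reduction with the twist (clearing) optimization:
// dimensions are processed from the top down, and the pivot row of each
// reduced column is cleared so it is never reduced itself. Simplices must
// arrive sorted by (filtration value, dimension, vertex order); vertices
// are 0-based and sorted within each simplex.

static inline uint64_t simplex_key(const int *v, int len) {
  uint64_t key = 0;
  for (int i = 0; i < len; ++i) {
    key = (key << 16) | (uint64_t)(v[i] + 1);
  }
  return key;
}

static void sym_diff(std::vector<int> &a, const std::vector<int> &b,
                     std::vector<int> &scratch) {
  scratch.clear();
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(scratch));
  a.swap(scratch);
}

// verts: concatenated 0-based vertex ids (sorted within each simplex)
// offsets: 0-based start positions, length n_simplices + 1
// filt: filtration value per simplex (birth step)
// [[Rcpp::export(name = ".reduce_filtration")]]
NumericMatrix reduce_filtration(IntegerVector verts, IntegerVector offsets,
                                NumericVector filt, int max_hom_dim,
                                bool drop_zero) {
  const int n = offsets.size() - 1;
  std::vector<int> dim(n);
  int maxd = 0;
  std::unordered_map<uint64_t, int> index_of;
  index_of.reserve((size_t)n * 2);
  for (int i = 0; i < n; ++i) {
    int len = offsets[i + 1] - offsets[i];
    dim[i] = len - 1;
    if (dim[i] > maxd) maxd = dim[i];
    index_of[simplex_key(&verts[offsets[i]], len)] = i;
  }

  std::vector<int> pivot_of_row(n, -1);
  std::vector<char> paired(n, 0), cleared(n, 0);
  std::vector<std::vector<int> > colstore(n);
  std::vector<double> out_dim, out_birth, out_death;
  std::vector<int> face(maxd + 1);
  std::vector<int> col, scratch;
  if (maxd + 1 > 4) stop("simplices above dimension 3 are not supported");

  for (int d = maxd; d >= 1; --d) {
    for (int j = 0; j < n; ++j) {
      if (dim[j] != d || cleared[j]) continue;
      const int len = d + 1;
      const int *sv = &verts[offsets[j]];
      col.clear();
      for (int drop = 0; drop < len; ++drop) {
        int fi = 0;
        for (int t = 0; t < len; ++t) {
          if (t != drop) face[fi++] = sv[t];
        }
        std::unordered_map<uint64_t, int>::const_iterator it =
          index_of.find(simplex_key(&face[0], len - 1));
        if (it == index_of.end()) stop("face missing from complex");
        col.push_back(it->second);
      }
      std::sort(col.begin(), col.end());
      while (!col.empty()) {
        int low = col.back();
        int k = pivot_of_row[low];
        if (k < 0) {
          pivot_of_row[low] = j;
          colstore[j] = col;
          paired[low] = 1;
          paired[j] = 1;
          cleared[low] = 1;
          if (d - 1 <= max_hom_dim &&
              (!drop_zero || filt[j] > filt[low])) {
            out_dim.push_back(d - 1);
            out_birth.push_back(filt[low]);
            out_death.push_back(filt[j]);
          }
          break;
        }
        sym_diff(col, colstore[k], scratch);
      }
      // empty column: j creates a d-cycle; it is paired (and was recorded)
      // only if some (d+1)-column already claimed it as a pivot row
    }
  }

  for (int j = 0; j < n; ++j) {
    if (!paired[j] && dim[j] <= max_hom_dim) {
      out_dim.push_back(dim[j]);
      out_birth.push_back(filt[j]);
      out_death.push_back(R_PosInf);
    }
  }

  const int m = (int)out_dim.size();
  NumericMatrix res(m, 3);
  for (int i = 0; i < m; ++i) {
    res(i, 0) = out_dim[i];
    res(i, 1) = out_birth[i];
    res(i, 2) = out_death[i];
  }
  colnames(res) = CharacterVector::create("dim", "birth", "death");
  return res;
}
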