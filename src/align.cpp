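// Unit-cost global alignment (Levenshtein) with deterministic traceback.
//
// Rows index the design, columns the product. Traceback preference:
// match > substitute > delete (design base absent from product) >
// insert (extra product base).

#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

static void dp_fill(const std::string& d, const std::string& p,
                    std::vector<int>& D, int m, int n) {
  // D is (m+1) x (n+1), row-major
  for (int j = 0; j <= n; ++j) D[j] = j;
  for (int i = 1; i <= m; ++i) {
    D[i * (n + 1)] = i;
    for (int j = 1; j <= n; ++j) {
      int diag = D[(i - 1) * (n + 1) + (j - 1)] + (d[i - 1] != p[j - 1]);
      int up   = D[(i - 1) * (n + 1) + j] + 1;       // delete design base
      int left = D[i * (n + 1) + (j - 1)] + 1;       // insert product base
      int best = diag < up ? diag : up;
      if (left < best) best = left;
      D[i * (n + 1) + j] = best;
    }
  }
}

// [[Rcpp::export(name = ".nwAlign")]]
List nwAlign(std::string design, std::string product) {
  int m = design.size(), n = product.size();
  std::vector<int> D((m + 1) * (n + 1));
  dp_fill(design, product, D, m, n);

  std::vector<std::string> ops;
  ops.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    int cur = D[i * (n + 1) + j];
    bool same = i > 0 && j > 0 && design[i - 1] == product[j - 1];
    if (i > 0 && j > 0 && same &&
        cur == D[(i - 1) * (n + 1) + (j - 1)]) {
      ops.push_back("match"); --i; --j;
    } else if (i > 0 && j > 0 && !same &&
               cur == D[(i - 1) * (n + 1) + (j - 1)] + 1) {
      ops.push_back("substitute"); --i; --j;
    } else if (i > 0 && cur == D[(i - 1) * (n + 1) + j] + 1) {
      ops.push_back("delete"); --i;
    } else {
      ops.push_back("insert"); --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = wrap(ops),
                      _["cost"] = D[m * (n + 1) + n]);
}

// Edit-op counts for many product/design pairs (fast path for statistics).
// [[Rcpp::export(name = ".nwCounts")]]
IntegerMatrix nwCounts(CharacterVector designs, CharacterVector prods) {
  int N = designs.size();
  IntegerMatrix out(N, 4);  // del, ins, sub, cost
  colnames(out) = CharacterVector::create("del", "ins", "sub", "cost");
  std::vector<int> D;
  for (int k = 0; k < N; ++k) {
    std::string d = as<std::string>(designs[k]);
    std::string p = as<std::string>(prods[k]);
    int m = d.size(), n = p.size();
    D.assign((m + 1) * (n + 1), 0);
    dp_fill(d, p, D, m, n);
    int i = m, j = n, del = 0, ins = 0, sub = 0;
    while (i > 0 || j > 0) {
      int cur = D[i * (n + 1) + j];
      bool same = i > 0 && j > 0 && d[i - 1] == p[j - 1];
      if (i > 0 && j > 0 && same && cur == D[(i - 1) * (n + 1) + (j - 1)]) {
        --i; --j;
      } else if (i > 0 && j > 0 && !same &&
                 cur == D[(i - 1) * (n + 1) + (j - 1)] + 1) {
        ++sub; --i; --j;
      } else if (i > 0 && cur == D[(i - 1) * (n + 1) + j] + 1) {
        ++del; --i;
      } else {
        ++ins; --j;
      }
    }
    out(k, 0) = del; out(k, 1) = ins; out(k, 2) = sub;
    out(k, 3) = D[m * (n + 1) + n];
  }
  return out;
}
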