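#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <tuple>

using namespace Rcpp;

// Multi-source Dijkstra over the 4-connected pixel graph. A step from
// pixel p to neighbor q costs sqrt(lambda^2 + (I(p) - I(q))^2); each
// foreground pixel takes the label of the seed reachable at minimal
// total cost. Ties are broken toward the lower label id (the heap pops
// equal-cost entries in label order). Non-foreground pixels stay 0.
// [[Rcpp::export(name = ".propagate_cpp")]]
IntegerVector propagate_cpp(IntegerMatrix seeds, NumericMatrix guide,
                            LogicalMatrix foreground, double lambda) {
  const int h = seeds.nrow(), w = seeds.ncol();
  const int n = h * w;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> lab(n, 0);
  std::vector<char> done(n, 0);

  typedef std::tuple<double, int, int> Node; // cost, label, index
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      int idx = r + c * h;
      if (seeds(r, c) > 0) {
        dist[idx] = 0.0;
        lab[idx] = seeds(r, c);
        pq.push(Node(0.0, seeds(r, c), idx));
      }
    }

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    double d = std::get<0>(nd);
    int l = std::get<1>(nd), idx = std::get<2>(nd);
    if (done[idx]) continue;
    if (d > dist[idx] || (d == dist[idx] && l != lab[idx])) continue;
    done[idx] = 1;
    int r = idx % h, c = idx / h;
    double gp = guide(r, c);
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
      int j = rr + cc * h;
      if (done[j] || !foreground(rr, cc) || seeds(rr, cc) > 0) continue;
      double dg = gp - guide(rr, cc);
      double nd2 = d + std::sqrt(lambda * lambda + dg * dg);
      if (nd2 < dist[j] || (nd2 == dist[j] && l < lab[j])) {
        dist[j] = nd2;
        lab[j] = l;
        pq.push(Node(nd2, l, j));
      }
    }
  }

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = done[i] ? lab[i] : 0;
  out.attr("dim") = Dimension(h, w);
  return out;
}
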