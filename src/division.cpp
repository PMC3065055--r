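#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// One day's division sweep. Tumour states are 3/4/5 (proliferative /
// hypoxic / necrotic); a daughter goes to the dividing cell's nearest
// neighbour, and an occupied neighbour triggers an outward push: labels
// shift along the shortest adjacency path through the tumour to the
// nearest non-tumour cell. The path field is one multi-source BFS from all
// non-tumour cells (deterministic: id order); paths invalidated by earlier
// pushes the same day are repaired with a local BFS.
//
// adj_ptr/adj_idx: CSR adjacency (0-based ptr into 1-based neighbour ids).
// divide: candidate dividing cells in processing order (1-based).
// [[Rcpp::export]]
List divide_cells_cpp(IntegerVector adj_ptr, IntegerVector adj_idx,
                      IntegerVector states, IntegerVector divide,
                      IntegerVector nearest) {
  const int n = states.size();
  IntegerVector st = clone(states);
  auto is_tumor = [&](int c) { return st[c] >= 3; };

  // flow field: next[c] = neighbour of c one step closer to a free cell
  std::vector<int> nxt(n, -1);
  {
    std::vector<char> assigned(n, 0);
    std::vector<int> frontier, newf;
    for (int c = 0; c < n; ++c) {
      if (!is_tumor(c)) { assigned[c] = 1; continue; }
    }
    for (int c = 0; c < n; ++c) {
      if (!is_tumor(c)) continue;
      for (int k = adj_ptr[c]; k < adj_ptr[c + 1]; ++k) {
        int nb = adj_idx[k] - 1;
        if (!is_tumor(nb)) { nxt[c] = nb; frontier.push_back(c); break; }
      }
    }
    for (int c : frontier) assigned[c] = 1;
    while (!frontier.empty()) {
      newf.clear();
      for (int cur : frontier) {
        for (int k = adj_ptr[cur]; k < adj_ptr[cur + 1]; ++k) {
          int nb = adj_idx[k] - 1;
          if (!assigned[nb]) {
            assigned[nb] = 1;
            nxt[nb] = cur;
            newf.push_back(nb);
          }
        }
      }
      frontier.swap(newf);
    }
  }

  // local repair: BFS from `from` through tumour cells to nearest free cell
  std::vector<int> bfs_parent(n), bfs_seen(n, -1);
  int stamp = 0;
  auto local_path = [&](int from, std::vector<int> &path) -> bool {
    ++stamp;
    std::queue<int> q;
    q.push(from);
    bfs_seen[from] = stamp;
    bfs_parent[from] = -1;
    while (!q.empty()) {
      int cur = q.front();
      q.pop();
      for (int k = adj_ptr[cur]; k < adj_ptr[cur + 1]; ++k) {
        int nb = adj_idx[k] - 1;
        if (bfs_seen[nb] == stamp) continue;
        bfs_seen[nb] = stamp;
        bfs_parent[nb] = cur;
        if (!is_tumor(nb)) {
          path.clear();
          for (int c = nb; c != -1; c = bfs_parent[c]) path.push_back(c);
          std::reverse(path.begin(), path.end()); // from .. free
          return true;
        }
        q.push(nb);
      }
    }
    return false;
  };

  int n_div = 0, lost = 0;
  std::vector<int> path, tailp;
  for (int i = 0; i < divide.size(); ++i) {
    int cell = divide[i] - 1;
    if (st[cell] != 3) continue; // displaced by an earlier push
    int nn = nearest[cell] - 1;
    if (nn < 0) continue;
    if (!is_tumor(nn)) {
      st[nn] = 3;
      ++n_div;
      continue;
    }
    // follow the flow field from nn; repair stale tails locally
    path.clear();
    path.push_back(nn);
    int cur = nn;
    bool ok = true;
    while (is_tumor(cur)) {
      int step = nxt[cur];
      if (step < 0) { // cell was free at day start or enclosed: repair
        if (!local_path(cur, tailp)) { ok = false; break; }
        path.insert(path.end(), tailp.begin() + 1, tailp.end());
        cur = path.back();
        break;
      }
      path.push_back(step);
      cur = step;
    }
    if (!ok || is_tumor(cur)) { ++lost; continue; }
    for (size_t k = path.size() - 1; k >= 1; --k) st[path[k]] = st[path[k - 1]];
    st[nn] = 3;
    ++n_div;
  }
  return List::create(_["states"] = st, _["n_divisions"] = n_div,
                      _["lost"] = lost);
}
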