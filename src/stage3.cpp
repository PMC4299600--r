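// Stage-3 search engine: exact minimum-node enumeration over candidate-path
// selections subject to mandatory pair coverage, frozen connection and hit
// optima, and consistent orientation of undirected edges.
//
// This mirrors the search described in R/ip_solve.R: depth-first over
// requirements (mandatory groups, connection pairs, hit nodes) with
// orientation-driven candidate elimination, an admissible node lower bound
// (uncovered mandatory endpoints + hit deficit + pair cost), unit
// propagation of single-candidate groups, exact dominance pruning of skip
// branches, and memoization of identical search states. mode 0 returns the
// minimal node count; mode 1 enumerates distinct optimal node sets (up to
// pool_size) with a representative selection each.

#include <Rcpp.h>
#include <unordered_set>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Engine {
  int nP = 0, nN = 0, nU = 0, nG = 0, nQ = 0, nH = 0, nR = 0;
  // CSR path data (0-based)
  std::vector<int> pn_off, pn;        // nodes per path
  std::vector<int> pu_off, pu, po;    // undirected edges per path + bit
  std::vector<int> g_off, g_cand;     // group candidates
  std::vector<int> g_ends;            // 2 endpoints per group
  std::vector<int> q_off, q_cand;     // pair candidates
  std::vector<int> hit_node;          // hit node index per hit
  std::vector<int> h_off, h_cand;     // hit candidates
  std::vector<int> p2g_off, p2g, p2q_off, p2q;
  std::vector<std::vector<int>> requirers0, requirers1; // per und edge
  std::vector<int> req_type, req_id;  // requirement list
  int conn_target = 0, hits_target = 0;
  int mode = 0;
  long pool_size = 0;

  // state
  std::vector<char> sel, alive, is_hit, in_needed;
  std::vector<int> und_val, und_cnt, node_cnt, grp_cnt, pair_cnt;
  std::vector<int> sel_stack;
  std::vector<std::vector<int>> kill_stack;
  int nn_cur = 0, hits_cur = 0, conn_cur = 0;
  int best = -1;
  bool have_best = false;
  bool done = false;
  long n_expand = 0;
  std::unordered_set<std::string> seen;
  std::unordered_set<std::string> pool_keys;
  std::vector<std::vector<int>> pool_sel;
  std::vector<std::vector<int>> pool_orient;

  int new_node_count(int i) const {
    int c = 0;
    for (int k = pn_off[i]; k < pn_off[i + 1]; ++k)
      if (node_cnt[pn[k]] == 0) ++c;
    return c;
  }
  int new_orient_count(int i) const {
    int c = 0;
    for (int k = pu_off[i]; k < pu_off[i + 1]; ++k)
      if (und_val[pu[k]] < 0) ++c;
    return c;
  }

  void add_path(int i) {
    sel[i] = 1;
    sel_stack.push_back(i);
    kill_stack.emplace_back();
    std::vector<int>& killed = kill_stack.back();
    for (int k = pu_off[i]; k < pu_off[i + 1]; ++k) {
      int u = pu[k];
      if (und_cnt[u] == 0) {
        und_val[u] = po[k];
        const std::vector<int>& dead = po[k] == 1 ? requirers0[u] : requirers1[u];
        for (int d : dead) if (alive[d]) { alive[d] = 0; killed.push_back(d); }
      }
      und_cnt[u] += 1;
    }
    for (int k = pn_off[i]; k < pn_off[i + 1]; ++k) {
      int n = pn[k];
      if (node_cnt[n] == 0) {
        ++nn_cur;
        if (is_hit[n]) ++hits_cur;
      }
      node_cnt[n] += 1;
    }
    for (int k = p2g_off[i]; k < p2g_off[i + 1]; ++k) grp_cnt[p2g[k]] += 1;
    for (int k = p2q_off[i]; k < p2q_off[i + 1]; ++k) {
      int q = p2q[k];
      if (pair_cnt[q] == 0) ++conn_cur;
      pair_cnt[q] += 1;
    }
  }

  void remove_path(int i) {
    sel[i] = 0;
    sel_stack.pop_back();
    for (int d : kill_stack.back()) alive[d] = 1;
    kill_stack.pop_back();
    for (int k = pu_off[i]; k < pu_off[i + 1]; ++k) {
      int u = pu[k];
      und_cnt[u] -= 1;
      if (und_cnt[u] == 0) und_val[u] = -1;
    }
    for (int k = pn_off[i]; k < pn_off[i + 1]; ++k) {
      int n = pn[k];
      node_cnt[n] -= 1;
      if (node_cnt[n] == 0) {
        --nn_cur;
        if (is_hit[n]) --hits_cur;
      }
    }
    for (int k = p2g_off[i]; k < p2g_off[i + 1]; ++k) grp_cnt[p2g[k]] -= 1;
    for (int k = p2q_off[i]; k < p2q_off[i + 1]; ++k) {
      int q = p2q[k];
      pair_cnt[q] -= 1;
      if (pair_cnt[q] == 0) --conn_cur;
    }
  }

  // Admissible additive lower bound by disjoint charging: requirements are
  // visited in a fixed order; each is charged the minimum number of
  // new-and-unblocked nodes over its surviving candidates, after which
  // every new node of any of its candidates is blocked. Charged node sets
  // are disjoint, so for any feasible completion the charges of the
  // requirements it satisfies sum to at most the completion's new-node
  // count. Mandatory groups all charge; hits charge through their deficit
  // cheapest; pairs charge through their deficit cheapest.
  bool bound_ok(int r) {
    std::vector<int> blocked_undo;
    auto charge = [&](const std::vector<int>& off, const std::vector<int>& cv,
                      int id) -> int {
      int mn = -1;
      for (int k = off[id]; k < off[id + 1]; ++k) {
        int i = cv[k];
        if (!alive[i]) continue;
        int nc = 0;
        for (int t = pn_off[i]; t < pn_off[i + 1]; ++t) {
          int n = pn[t];
          if (node_cnt[n] == 0 && !in_needed[n]) ++nc;
        }
        if (mn < 0 || nc < mn) mn = nc;
      }
      if (mn < 0) return -1;  // no surviving candidate
      for (int k = off[id]; k < off[id + 1]; ++k) {
        int i = cv[k];
        if (!alive[i]) continue;
        for (int t = pn_off[i]; t < pn_off[i + 1]; ++t) {
          int n = pn[t];
          if (node_cnt[n] == 0 && !in_needed[n]) {
            in_needed[n] = 1;
            blocked_undo.push_back(n);
          }
        }
      }
      return mn;
    };
    auto fail = [&]() {
      for (int n : blocked_undo) in_needed[n] = 0;
      return false;
    };

    long additive = 0;
    for (int g = std::max(0, r); g < nG; ++g) {
      if (grp_cnt[g] > 0) continue;
      int c = charge(g_off, g_cand, g);
      if (c < 0) return fail();  // mandatory group unsatisfiable
      additive += c;
    }
    int hit_deficit = std::max(0, hits_target - hits_cur);
    {
      std::vector<int> hcharges;
      for (int h = 0; h < nH; ++h) {
        if (node_cnt[hit_node[h]] > 0) continue;
        int c = charge(h_off, h_cand, h);
        if (c >= 0) hcharges.push_back(c);
      }
      if ((int)hcharges.size() < hit_deficit) return fail();
      if (hit_deficit > 0) {
        std::nth_element(hcharges.begin(), hcharges.begin() + (hit_deficit - 1),
                         hcharges.end());
        for (int k = 0; k < hit_deficit; ++k) additive += hcharges[k];
      }
    }
    int conn_deficit = conn_target - conn_cur;
    {
      std::vector<int> qcharges;
      for (int q = 0; q < nQ; ++q) {
        if (pair_cnt[q] > 0) continue;
        int c = charge(q_off, q_cand, q);
        if (c >= 0) qcharges.push_back(c);
      }
      if ((int)qcharges.size() < conn_deficit) return fail();
      if (conn_deficit > 0) {
        std::nth_element(qcharges.begin(), qcharges.begin() + (conn_deficit - 1),
                         qcharges.end());
        for (int k = 0; k < conn_deficit; ++k) additive += qcharges[k];
      }
    }
    for (int n : blocked_undo) in_needed[n] = 0;

    long lb = nn_cur + additive;
    if (have_best) {
      if (mode == 0 && lb >= best) return false;
      if (mode == 1 && lb > best) return false;
    }
    return true;
  }

  std::string state_key(int r) const {
    std::string key;
    key.reserve(16 + nN / 8 + nU + nG / 8 + nQ / 8);
    key.push_back((char)(r & 0xff));
    key.push_back((char)((r >> 8) & 0xff));
    unsigned char acc = 0;
    int bit = 0;
    auto push_bit = [&](bool b) {
      acc = (unsigned char)((acc << 1) | (b ? 1 : 0));
      if (++bit == 8) { key.push_back((char)acc); acc = 0; bit = 0; }
    };
    for (int n = 0; n < nN; ++n) push_bit(node_cnt[n] > 0);
    for (int g = 0; g < nG; ++g) push_bit(grp_cnt[g] > 0);
    for (int q = 0; q < nQ; ++q) push_bit(pair_cnt[q] > 0);
    if (bit) key.push_back((char)(acc << (8 - bit)));
    for (int u = 0; u < nU; ++u) key.push_back((char)(und_val[u] + 1));
    return key;
  }

  std::string node_key() const {
    std::string key;
    key.reserve(nN / 8 + 1);
    unsigned char acc = 0;
    int bit = 0;
    for (int n = 0; n < nN; ++n) {
      acc = (unsigned char)((acc << 1) | (node_cnt[n] > 0 ? 1 : 0));
      if (++bit == 8) { key.push_back((char)acc); acc = 0; bit = 0; }
    }
    if (bit) key.push_back((char)(acc << (8 - bit)));
    return key;
  }

  bool is_sat(int r) const {
    int t = req_type[r], id = req_id[r];
    if (t == 0) return grp_cnt[id] > 0;
    if (t == 1) return pair_cnt[id] > 0;
    return node_cnt[hit_node[id]] > 0;
  }

  void recurse(int r) {
    if (done) return;
    while (r < nR && is_sat(r)) ++r;
    if (++n_expand % 1000000L == 0) {
      Rcpp::checkUserInterrupt();
      if (n_expand % 10000000L == 0)
        Rcout << "stage-3 search: " << n_expand / 1000000L << "M expansions, best "
              << best << ", memo " << seen.size() << "\n";
    }
    if (!bound_ok(r)) return;
    if (r >= nR) {
      if (conn_cur != conn_target || hits_cur != hits_target) return;
      if (mode == 0) {
        if (!have_best || nn_cur < best) { best = nn_cur; have_best = true; }
      } else if (nn_cur == best) {
        std::string key = node_key();
        if (pool_keys.insert(key).second) {
          pool_sel.push_back(sel_stack);
          pool_orient.push_back(und_val);
          if ((long)pool_sel.size() >= pool_size) done = true;
        }
      }
      return;
    }
    {
      std::string key = state_key(r);
      if (seen.count(key)) return;
      if (seen.size() < 30000000UL) seen.insert(std::move(key));
    }

    int t = req_type[r], id = req_id[r];
    const std::vector<int>& off = (t == 0) ? g_off : (t == 1) ? q_off : h_off;
    const std::vector<int>& cv = (t == 0) ? g_cand : (t == 1) ? q_cand : h_cand;
    std::vector<std::pair<int, int>> usable;  // (new nodes, path)
    for (int k = off[id]; k < off[id + 1]; ++k) {
      int i = cv[k];
      if (!sel[i] && alive[i]) usable.emplace_back(new_node_count(i), i);
    }
    std::sort(usable.begin(), usable.end());
    for (auto& pr : usable) {
      add_path(pr.second);
      recurse(r + 1);
      remove_path(pr.second);
      if (done) return;
    }
    if (t != 0) {
      bool free_exists = false;
      for (auto& pr : usable)
        if (pr.first == 0 && new_orient_count(pr.second) == 0) { free_exists = true; break; }
      if (!free_exists) recurse(r + 1);
    }
  }

  // unit propagation: single-candidate mandatory groups force their path
  void propagate() {
    bool changed = true;
    while (changed) {
      changed = false;
      for (int g = 0; g < nG; ++g) {
        if (grp_cnt[g] > 0) continue;
        int last = -1, cnt = 0;
        for (int k = g_off[g]; k < g_off[g + 1]; ++k) {
          int i = g_cand[k];
          if (alive[i]) { last = i; ++cnt; if (cnt > 1) break; }
        }
        if (cnt == 0) stop("infeasible: a mandatory pair has no orientation-compatible candidate path");
        if (cnt == 1) { add_path(last); changed = true; }
      }
    }
  }
};

std::vector<int> as_vec(IntegerVector v) {
  return std::vector<int>(v.begin(), v.end());
}

}  // namespace

// [[Rcpp::export(name = ".stage3_cpp")]]
List stage3_cpp(List flat, int conn_target, int hits_target, int mode,
                double best_nodes, double pool_size) {
  Engine e;
  e.nP = as<int>(flat["nP"]); e.nN = as<int>(flat["nN"]);
  e.nU = as<int>(flat["nU"]); e.nG = as<int>(flat["nG"]);
  e.nQ = as<int>(flat["nQ"]); e.nH = as<int>(flat["nH"]);
  e.pn_off = as_vec(flat["pn_off"]); e.pn = as_vec(flat["pn"]);
  e.pu_off = as_vec(flat["pu_off"]); e.pu = as_vec(flat["pu"]); e.po = as_vec(flat["po"]);
  e.g_off = as_vec(flat["g_off"]); e.g_cand = as_vec(flat["g_cand"]);
  e.g_ends = as_vec(flat["g_ends"]);
  e.q_off = as_vec(flat["q_off"]); e.q_cand = as_vec(flat["q_cand"]);
  e.hit_node = as_vec(flat["hit_node"]);
  e.h_off = as_vec(flat["h_off"]); e.h_cand = as_vec(flat["h_cand"]);
  e.p2g_off = as_vec(flat["p2g_off"]); e.p2g = as_vec(flat["p2g"]);
  e.p2q_off = as_vec(flat["p2q_off"]); e.p2q = as_vec(flat["p2q"]);
  e.req_type = as_vec(flat["req_type"]); e.req_id = as_vec(flat["req_id"]);
  e.nR = (int)e.req_type.size();
  e.conn_target = conn_target; e.hits_target = hits_target;
  e.mode = mode;
  e.pool_size = (pool_size > 2e9) ? (long)4e18 : (long)pool_size;

  e.requirers0.assign(std::max(e.nU, 1), {});
  e.requirers1.assign(std::max(e.nU, 1), {});
  for (int i = 0; i < e.nP; ++i)
    for (int k = e.pu_off[i]; k < e.pu_off[i + 1]; ++k) {
      if (e.po[k] == 0) e.requirers0[e.pu[k]].push_back(i);
      else e.requirers1[e.pu[k]].push_back(i);
    }

  e.sel.assign(e.nP, 0);
  e.alive.assign(e.nP, 1);
  e.und_val.assign(std::max(e.nU, 1), -1);
  e.und_cnt.assign(std::max(e.nU, 1), 0);
  e.node_cnt.assign(std::max(e.nN, 1), 0);
  e.grp_cnt.assign(std::max(e.nG, 1), 0);
  e.pair_cnt.assign(std::max(e.nQ, 1), 0);
  e.is_hit.assign(std::max(e.nN, 1), 0);
  e.in_needed.assign(std::max(e.nN, 1), 0);
  IntegerVector hidx = flat["hit_node"];
  for (int k = 0; k < hidx.size(); ++k) e.is_hit[hidx[k]] = 1;

  if (R_finite(best_nodes)) { e.best = (int)best_nodes; e.have_best = true; }

  e.propagate();
  e.recurse(0);

  if (mode == 0) {
    if (!e.have_best) stop("infeasible: stage 3 found no solution meeting the stage freezes");
    return List::create(_["min_nodes"] = e.best, _["n_expand"] = (double)e.n_expand);
  }
  List sel_out(e.pool_sel.size()), or_out(e.pool_orient.size());
  for (size_t k = 0; k < e.pool_sel.size(); ++k) {
    IntegerVector s(e.pool_sel[k].begin(), e.pool_sel[k].end());
    sel_out[k] = s + 1;  // back to 1-based path indices
    IntegerVector o(e.pool_orient[k].begin(), e.pool_orient[k].end());
    or_out[k] = o;
  }
  return List::create(_["sel"] = sel_out, _["orient"] = or_out,
                      _["n_expand"] = (double)e.n_expand);
}
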