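#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

// Exact assembly-index search.
//
// An assembly pathway that builds the target from its single characters by
// binary concatenation joins (reuse free) is equivalent to a set S of
// fragments with target in S such that every element of S splits into two
// parts, each a single character or another element of S: products are
// strictly longer than their operands, so ordering S by length always gives
// a valid join sequence, and the assembly index is min |S|.  In a minimal
// pathway every fragment is used inside the target, hence occurs
// contiguously in it, so S ranges over distinct substrings of the target.
//
// The search is top-down branch-and-bound: resolve the longest unresolved
// fragment by branching over its split points, adding missing parts to S.
// Pruning uses
//   - the current best (initialised from the caller's upper bound),
//   - a doubling bound: fragment lengths can at most double per new
//     element, so a long unresolved fragment needs at least
//     ceil(log2(len / (2 * Lmax))) further elements,
//   - a visited-state table (S, unresolved) -- sound because a state's
//     optimal completion does not depend on how it was reached.
// Branching order is canonical, so results and witnesses are deterministic.

namespace {

typedef std::vector<uint64_t> Bits;

inline bool get_bit(const Bits &bs, int i) {
    return (bs[i >> 6] >> (i & 63)) & 1ULL;
}
inline void set_bit(Bits &bs, int i) { bs[i >> 6] |= 1ULL << (i & 63); }
inline void clear_bit(Bits &bs, int i) {
    bs[i >> 6] &= ~(1ULL << (i & 63));
}

// open-addressing set of fixed-width state keys (inset + unresolved words)
struct StateSet {
    std::vector<uint64_t> slots;  // key_words per entry
    std::vector<uint8_t> used;
    size_t capacity = 0;
    size_t count = 0;
    int key_words = 0;

    void init(int kw) {
        key_words = kw;
        capacity = 1 << 16;
        slots.assign(capacity * key_words, 0);
        used.assign(capacity, 0);
        count = 0;
    }
    static uint64_t mix(uint64_t x) {
        x += 0x9e3779b97f4a7c15ULL;
        x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
        x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
        return x ^ (x >> 31);
    }
    // returns true if the key was newly inserted
    bool insert(const uint64_t *key) {
        if (count * 10 >= capacity * 7) grow();
        uint64_t h = 0;
        for (int i = 0; i < key_words; ++i) h = mix(h ^ key[i]);
        size_t pos = h & (capacity - 1);
        for (;;) {
            if (!used[pos]) {
                used[pos] = 1;
                std::copy(key, key + key_words, &slots[pos * key_words]);
                ++count;
                return true;
            }
            if (std::equal(key, key + key_words, &slots[pos * key_words])) {
                return false;
            }
            pos = (pos + 1) & (capacity - 1);
        }
    }
    void grow() {
        std::vector<uint64_t> old_slots;
        std::vector<uint8_t> old_used;
        old_slots.swap(slots);
        old_used.swap(used);
        size_t old_cap = capacity;
        capacity <<= 1;
        slots.assign(capacity * key_words, 0);
        used.assign(capacity, 0);
        count = 0;
        for (size_t i = 0; i < old_cap; ++i) {
            if (old_used[i]) insert(&old_slots[i * key_words]);
        }
    }
};

struct Ctx {
    int n;          // substrings of length >= 2, canonical order
    int words;
    int target_id;
    std::vector<std::string> sub;
    std::vector<int> len;
    // splits[w]: decompositions (u, v) with ids, -1 for a single character
    std::vector<std::vector<std::array<int, 2>>> splits;
    int best;                      // size of best solution found so far
    int floor_size;                // stop improving below this (lower bound)
    std::vector<std::array<int, 2>> chosen;  // current decomposition per id
    std::vector<std::array<int, 2>> best_dec;
    Bits best_inset;
    bool have_best;
    StateSet visited;
    Bits keybuf, e1buf, interbuf;
    long long nodes;
    long long node_limit;
    bool aborted;
};

int popcount(const Bits &b) {
    int c = 0;
    for (uint64_t w : b) c += __builtin_popcountll(w);
    return c;
}

// least number of extra elements needed to reach length `need` when the
// longest usable fragment has length `have` (lengths at most double per
// new element)
int doubling_gap(int need, int have) {
    int extra = 0;
    long long reach = 2LL * have;
    while (reach < need) {
        reach <<= 1;
        ++extra;
    }
    return extra;
}

inline int split_cost(const Ctx &ctx, const Bits &inset,
                      const std::array<int, 2> &sp) {
    int nw = 0;
    if (sp[0] >= 0 && !get_bit(inset, sp[0])) ++nw;
    if (sp[1] >= 0 && !get_bit(inset, sp[1]) && sp[1] != sp[0]) ++nw;
    return nw;
}

void dfs(Ctx &ctx, Bits &inset, Bits &unresolved, int size) {
    if (ctx.aborted || ++ctx.nodes > ctx.node_limit) {
        ctx.aborted = true;
        return;
    }
    if (size >= ctx.best) return;

    // Forced resolutions: any unresolved fragment with a split whose parts
    // are all already available can take that split at zero cost -- any
    // completion can be re-pointed to it without growing, so no branching
    // is needed.  Such resolutions do not change the available set, so one
    // pass suffices.
    std::vector<int> forced;
    std::vector<int> open;
    for (int word = 0; word < ctx.words; ++word) {
        uint64_t bits = unresolved[word];
        while (bits) {
            int u = (word << 6) + __builtin_ctzll(bits);
            bits &= bits - 1;
            const std::vector<std::array<int, 2>> &sp = ctx.splits[u];
            int zero = -1;
            for (int i = 0; i < static_cast<int>(sp.size()); ++i) {
                if (split_cost(ctx, inset, sp[i]) == 0) {
                    zero = i;
                    break;
                }
            }
            if (zero >= 0) {
                ctx.chosen[u] = sp[zero];
                forced.push_back(u);
            } else {
                open.push_back(u);
            }
        }
    }
    for (int f : forced) clear_bit(unresolved, f);

    if (open.empty()) {  // complete: every chosen fragment is decomposed
        ctx.best = size;
        ctx.best_dec = ctx.chosen;
        ctx.best_inset = inset;
        ctx.have_best = true;
        for (int f : forced) set_bit(unresolved, f);
        return;
    }

    // every remaining fragment needs >= 1 new part; slack = how many new
    // fragments a strictly better solution may still add
    const int slack = ctx.best - 1 - size;
    bool dead = slack <= 0;

    if (!dead && slack == 1) {
        // exactly one new element may be added: it must complete a split
        // of every open fragment and itself be buildable from what is
        // available -- solvable directly by set intersection
        Bits &inter = ctx.interbuf;
        Bits &e1 = ctx.e1buf;
        std::fill(inter.begin(), inter.end(), ~0ULL);
        for (int u : open) {
            std::fill(e1.begin(), e1.end(), 0ULL);
            for (const std::array<int, 2> &sp : ctx.splits[u]) {
                if (split_cost(ctx, inset, sp) != 1) continue;
                int p = (sp[0] >= 0 && !get_bit(inset, sp[0])) ? sp[0] : sp[1];
                set_bit(e1, p);
            }
            bool any = false;
            for (int j = 0; j < ctx.words; ++j) {
                inter[j] &= e1[j];
                if (inter[j]) any = true;
            }
            if (!any) break;
        }
        for (int word = 0; word < ctx.words; ++word) {
            uint64_t bits = inter[word];
            while (bits) {
                int e = (word << 6) + __builtin_ctzll(bits);
                bits &= bits - 1;
                if (e >= ctx.n) continue;
                int zero = -1;
                for (int i = 0; i < static_cast<int>(ctx.splits[e].size());
                     ++i) {
                    if (split_cost(ctx, inset, ctx.splits[e][i]) == 0) {
                        zero = i;
                        break;
                    }
                }
                if (zero < 0) continue;
                // found: record the completed solution
                ctx.chosen[e] = ctx.splits[e][zero];
                for (int u : open) {
                    for (const std::array<int, 2> &sp : ctx.splits[u]) {
                        if (split_cost(ctx, inset, sp) == 1) {
                            int p = (sp[0] >= 0 && !get_bit(inset, sp[0]))
                                        ? sp[0]
                                        : sp[1];
                            if (p == e) {
                                ctx.chosen[u] = sp;
                                break;
                            }
                        }
                    }
                }
                set_bit(inset, e);
                ctx.best = size + 1;
                ctx.best_dec = ctx.chosen;
                ctx.best_inset = inset;
                ctx.have_best = true;
                clear_bit(inset, e);
                word = ctx.words;  // done
                break;
            }
        }
        for (int f : forced) set_bit(unresolved, f);
        return;
    }

    // doubling bound against the longest shorter available fragment
    // (open[0] has the smallest id, i.e. is the longest unresolved)
    if (!dead) {
        int wl = ctx.len[open[0]];
        int have = 1;
        for (int i = open[0] + 1; i < ctx.n; ++i) {
            if (ctx.len[i] < wl && get_bit(inset, i)) {
                have = ctx.len[i];
                break;
            }
        }
        if (doubling_gap(wl, have) > slack) dead = true;
    }

    // most-constrained fragment: fewest affordable splits
    int w = -1;
    int w_opts = INT32_MAX;
    if (!dead) {
        for (int u : open) {
            int opts = 0;
            for (const std::array<int, 2> &sp : ctx.splits[u]) {
                if (split_cost(ctx, inset, sp) <= slack) ++opts;
            }
            if (opts == 0) {
                dead = true;
                break;
            }
            if (opts < w_opts) {
                w_opts = opts;
                w = u;
            }
        }
    }

    // hitting-set bound: every open fragment must acquire at least one new
    // part drawn from its affordable splits; fragments whose candidate
    // part sets are pairwise disjoint need pairwise distinct new parts
    if (!dead && ctx.words <= 4 && open.size() > 1) {
        uint64_t cand[64][4];
        int sz[64];
        const int m = std::min<int>(static_cast<int>(open.size()), 64);
        for (int k = 0; k < m; ++k) {
            uint64_t *msk = cand[k];
            msk[0] = msk[1] = msk[2] = msk[3] = 0;
            for (const std::array<int, 2> &sp : ctx.splits[open[k]]) {
                if (split_cost(ctx, inset, sp) > slack) continue;
                for (int j = 0; j < 2; ++j) {
                    int p = sp[j];
                    if (p >= 0 && !get_bit(inset, p)) {
                        msk[p >> 6] |= 1ULL << (p & 63);
                    }
                }
            }
            sz[k] = __builtin_popcountll(msk[0]) +
                    __builtin_popcountll(msk[1]) +
                    __builtin_popcountll(msk[2]) +
                    __builtin_popcountll(msk[3]);
        }
        int idx[64];
        for (int k = 0; k < m; ++k) idx[k] = k;
        std::sort(idx, idx + m, [&sz](int a, int b) { return sz[a] < sz[b]; });
        uint64_t acc[4] = {0, 0, 0, 0};
        int need = 0;
        for (int k = 0; k < m; ++k) {
            const uint64_t *msk = cand[idx[k]];
            if (!((msk[0] & acc[0]) | (msk[1] & acc[1]) |
                  (msk[2] & acc[2]) | (msk[3] & acc[3]))) {
                ++need;
                acc[0] |= msk[0];
                acc[1] |= msk[1];
                acc[2] |= msk[2];
                acc[3] |= msk[3];
            }
        }
        if (need > slack) dead = true;
    }

    if (!dead) {
        std::copy(inset.begin(), inset.end(), ctx.keybuf.begin());
        std::copy(unresolved.begin(), unresolved.end(),
                  ctx.keybuf.begin() + ctx.words);
        if (!ctx.visited.insert(ctx.keybuf.data())) dead = true;
    }
    if (dead) {
        for (int f : forced) set_bit(unresolved, f);
        return;
    }

    clear_bit(unresolved, w);

    // order split points: fewest new fragments first, then position
    const std::vector<std::array<int, 2>> &sp = ctx.splits[w];
    std::vector<std::array<int, 2>> order;  // (new-part count, split idx)
    order.reserve(sp.size());
    for (int i = 0; i < static_cast<int>(sp.size()); ++i) {
        int nw = split_cost(ctx, inset, sp[i]);
        if (nw <= slack) order.push_back({nw, i});
    }
    std::stable_sort(order.begin(), order.end());

    for (const std::array<int, 2> &o : order) {
        if (o[0] > ctx.best - 1 - size) break;  // best may have improved
        int u = sp[o[1]][0], v = sp[o[1]][1];
        int added[2] = {-1, -1};
        int na = 0;
        if (u >= 0 && !get_bit(inset, u)) {
            set_bit(inset, u);
            set_bit(unresolved, u);
            added[na++] = u;
        }
        if (v >= 0 && !get_bit(inset, v)) {
            set_bit(inset, v);
            set_bit(unresolved, v);
            added[na++] = v;
        }
        ctx.chosen[w] = {u, v};
        dfs(ctx, inset, unresolved, size + na);
        for (int j = 0; j < na; ++j) {
            clear_bit(inset, added[j]);
            clear_bit(unresolved, added[j]);
        }
        if (ctx.best <= ctx.floor_size || ctx.aborted) break;
    }

    set_bit(unresolved, w);
    for (int f : forced) set_bit(unresolved, f);
}

} // namespace

// Search for an assembly pathway of `target` with at most `max_depth`
// joins, `min_depth` being a proven lower bound.  Returns found = FALSE if
// no pathway with <= max_depth joins exists (or, with complete = FALSE, if
// the node budget was exhausted first).
// [[Rcpp::export]]
Rcpp::List cpp_assembly_search(std::string target, int min_depth,
                               int max_depth,
                               double node_limit = 1e18) {
    Ctx ctx;
    const int tlen = static_cast<int>(target.size());

    std::vector<std::string> all;
    for (int i = 0; i < tlen; ++i)
        for (int j = i + 2; j <= tlen; ++j)
            all.push_back(target.substr(i, j - i));
    std::sort(all.begin(), all.end(),
              [](const std::string &a, const std::string &b) {
                  if (a.size() != b.size()) return a.size() > b.size();
                  return a < b;
              });
    all.erase(std::unique(all.begin(), all.end()), all.end());
    ctx.sub = std::move(all);
    ctx.n = static_cast<int>(ctx.sub.size());
    ctx.words = (ctx.n + 63) / 64;

    std::unordered_map<std::string, int> id;
    for (int i = 0; i < ctx.n; ++i) {
        id[ctx.sub[i]] = i;
        ctx.len.push_back(static_cast<int>(ctx.sub[i].size()));
    }
    ctx.target_id = id[target];

    ctx.splits.resize(ctx.n);
    for (int w = 0; w < ctx.n; ++w) {
        const std::string &s = ctx.sub[w];
        const int m = static_cast<int>(s.size());
        // splits imposing the same unordered part requirements are
        // interchangeable in any solution; keep only the leftmost
        std::unordered_set<long long> seen;
        for (int i = 1; i < m; ++i) {
            int u = (i == 1) ? -1 : id[s.substr(0, i)];
            int v = (i == m - 1) ? -1 : id[s.substr(i)];
            // content code: single characters get negative codes
            long long cu = (u >= 0) ? u : -static_cast<int>(s[0]) - 2;
            long long cv = (v >= 0) ? v : -static_cast<int>(s[m - 1]) - 2;
            long long key = ((std::min(cu, cv) + 1024) << 32) |
                            (std::max(cu, cv) + 1024);
            if (seen.insert(key).second) ctx.splits[w].push_back({u, v});
        }
    }

    ctx.visited.init(2 * ctx.words);
    ctx.keybuf.assign(2 * ctx.words, 0);
    ctx.e1buf.assign(ctx.words, 0);
    ctx.interbuf.assign(ctx.words, 0);
    ctx.best = max_depth + 1;
    ctx.floor_size = std::max(min_depth, 1);
    ctx.have_best = false;
    ctx.chosen.assign(ctx.n, {-1, -1});
    ctx.nodes = 0;
    ctx.node_limit = (node_limit > 9e18) ? 9000000000000000000LL
                                         : static_cast<long long>(node_limit);
    ctx.aborted = false;

    Bits inset(ctx.words, 0), unresolved(ctx.words, 0);
    set_bit(inset, ctx.target_id);
    set_bit(unresolved, ctx.target_id);
    dfs(ctx, inset, unresolved, 1);

    if (!ctx.have_best) {
        return Rcpp::List::create(Rcpp::Named("found") = false,
                                  Rcpp::Named("depth") = NA_INTEGER,
                                  Rcpp::Named("complete") = !ctx.aborted);
    }

    // emit the witness: chosen fragments ordered by increasing length
    std::vector<int> members;
    for (int i = 0; i < ctx.n; ++i)
        if (get_bit(ctx.best_inset, i)) members.push_back(i);
    std::sort(members.begin(), members.end(), [&ctx](int a, int b) {
        if (ctx.len[a] != ctx.len[b]) return ctx.len[a] < ctx.len[b];
        return ctx.sub[a] < ctx.sub[b];
    });
    const int k = static_cast<int>(members.size());
    Rcpp::CharacterVector left(k), right(k), product(k);
    for (int i = 0; i < k; ++i) {
        int w = members[i];
        int u = ctx.best_dec[w][0], v = ctx.best_dec[w][1];
        const std::string &s = ctx.sub[w];
        std::string us = (u >= 0) ? ctx.sub[u] : s.substr(0, 1);
        left[i] = us;
        right[i] = (v >= 0) ? ctx.sub[v] : s.substr(s.size() - 1, 1);
        product[i] = s;
    }
    return Rcpp::List::create(
        Rcpp::Named("found") = true, Rcpp::Named("depth") = k,
        Rcpp::Named("complete") = !ctx.aborted, Rcpp::Named("left") = left,
        Rcpp::Named("right") = right, Rcpp::Named("product") = product);
}
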