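#include <Rcpp.h>
#include <map>
#include <vector>
#include <utility>

// Sequitur grammar induction, generalised to a digram-promotion threshold K.
//
// Symbol convention: positive int = terminal behavior code,
// negative int = reference to rule (-index) in `rules`; rules[0] is the
// start sequence R0 and is never referenced.
//
// Formulation: online append of each terminal to R0 followed by a
// deterministic fixed point that (1) substitutes any digram matching the
// complete right-hand side of an existing length-2 rule, (2) promotes the
// first digram (rules scanned in index order, positions left to right) with
// >= K greedy non-overlapping occurrences to a new rule, and (3) inlines
// any rule referenced fewer than K times. With K = 2 this enforces the
// classical digram-uniqueness and rule-utility constraints.

namespace {

struct Occ {
  int rule;
  int pos;
};

typedef std::pair<int, int> Digram;

class Builder {
public:
  explicit Builder(int k) : k_(k) {
    rules_.push_back(std::vector<int>());  // R0
    alive_.push_back(true);
  }

  void append(int terminal) {
    rules_[0].push_back(terminal);
    fixpoint();
  }

  Rcpp::List finish() const {
    // renumber surviving rules 1..n in creation order
    std::vector<int> newid(rules_.size(), 0);
    int next = 0;
    for (size_t r = 1; r < rules_.size(); ++r)
      if (alive_[r]) newid[r] = ++next;

    Rcpp::List out_rules(next);
    Rcpp::CharacterVector nm(next);
    for (size_t r = 1; r < rules_.size(); ++r) {
      if (!alive_[r]) continue;
      out_rules[newid[r] - 1] = remap(rules_[r], newid);
      nm[newid[r] - 1] = std::to_string(newid[r]);
    }
    out_rules.attr("names") = nm;
    return Rcpp::List::create(Rcpp::Named("start") = remap(rules_[0], newid),
                              Rcpp::Named("rules") = out_rules);
  }

private:
  int k_;
  std::vector<std::vector<int> > rules_;
  std::vector<bool> alive_;

  static Rcpp::IntegerVector remap(const std::vector<int>& syms,
                                   const std::vector<int>& newid) {
    Rcpp::IntegerVector out(syms.size());
    for (size_t i = 0; i < syms.size(); ++i)
      out[i] = syms[i] > 0 ? syms[i] : -newid[-syms[i]];
    return out;
  }

  void fixpoint() {
    const int guard = 1000000;
    for (int it = 0; it < guard; ++it) {
      if (enforce_digrams()) continue;
      if (enforce_utility()) continue;
      return;
    }
    Rcpp::stop("sequitur fixed point did not converge");  // unreachable
  }

  // scan digrams in deterministic order; returns true if a rewrite happened
  bool enforce_digrams() {
    std::map<Digram, std::vector<Occ> > occ;
    std::vector<Digram> order;
    for (size_t r = 0; r < rules_.size(); ++r) {
      if (!alive_[r]) continue;
      const std::vector<int>& s = rules_[r];
      for (size_t p = 0; p + 1 < s.size(); ++p) {
        Digram d(s[p], s[p + 1]);
        std::map<Digram, std::vector<Occ> >::iterator hit = occ.find(d);
        if (hit == occ.end()) order.push_back(d);
        Occ o;
        o.rule = (int)r;
        o.pos = (int)p;
        occ[d].push_back(o);
      }
    }

    // map complete length-2 RHSs to their rule ids
    std::map<Digram, int> defined;
    for (size_t r = 1; r < rules_.size(); ++r)
      if (alive_[r] && rules_[r].size() == 2)
        defined[Digram(rules_[r][0], rules_[r][1])] = (int)r;

    for (size_t i = 0; i < order.size(); ++i) {
      const Digram& d = order[i];
      const std::vector<Occ>& all = occ[d];

      std::map<Digram, int>::iterator def = defined.find(d);
      if (def != defined.end()) {
        // substitute the first occurrence outside the defining rule's own RHS
        int r = def->second;
        for (size_t j = 0; j < all.size(); ++j) {
          if (all[j].rule == r && rules_[r].size() == 2) continue;
          substitute(all[j].rule, all[j].pos, -r);
          return true;
        }
        continue;
      }

      // greedy non-overlapping occurrence count
      std::vector<Occ> picked;
      int last_rule = -1, last_pos = -2;
      for (size_t j = 0; j < all.size(); ++j) {
        if (all[j].rule == last_rule && all[j].pos <= last_pos + 1) continue;
        picked.push_back(all[j]);
        last_rule = all[j].rule;
        last_pos = all[j].pos;
      }
      if ((int)picked.size() >= k_) {
        std::vector<int> rhs;
        rhs.push_back(d.first);
        rhs.push_back(d.second);
        rules_.push_back(rhs);
        alive_.push_back(true);
        int rid = (int)rules_.size() - 1;
        // replace right to left so stored positions stay valid
        for (int j = (int)picked.size() - 1; j >= 0; --j)
          substitute(picked[j].rule, picked[j].pos, -rid);
        return true;
      }
    }
    return false;
  }

  bool enforce_utility() {
    std::vector<int> refs(rules_.size(), 0);
    for (size_t r = 0; r < rules_.size(); ++r) {
      if (!alive_[r]) continue;
      for (size_t p = 0; p < rules_[r].size(); ++p)
        if (rules_[r][p] < 0) refs[-rules_[r][p]]++;
    }
    for (size_t r = 1; r < rules_.size(); ++r) {
      if (!alive_[r] || refs[r] >= k_) continue;
      inline_rule((int)r);
      return true;
    }
    return false;
  }

  void substitute(int rule, int pos, int sym) {
    std::vector<int>& s = rules_[rule];
    s[pos] = sym;
    s.erase(s.begin() + pos + 1);
  }

  void inline_rule(int rid) {
    const std::vector<int> body = rules_[rid];
    for (size_t r = 0; r < rules_.size(); ++r) {
      if (!alive_[r] || (int)r == rid) continue;
      std::vector<int>& s = rules_[r];
      for (size_t p = 0; p < s.size();) {
        if (s[p] == -rid) {
          s.erase(s.begin() + p);
          s.insert(s.begin() + p, body.begin(), body.end());
          p += body.size();
        } else {
          ++p;
        }
      }
    }
    alive_[rid] = false;
  }
};

}  // namespace

// [[Rcpp::export(name = ".sequitur_induce")]]
Rcpp::List sequitur_induce(Rcpp::IntegerVector actions, int k) {
  if (actions.size() == 0) Rcpp::stop("cannot induce a grammar on an empty sequence");
  if (k < 2) Rcpp::stop("k must be >= 2");
  Builder b(k);
  for (int i = 0; i < actions.size(); ++i) {
    if (actions[i] < 1) Rcpp::stop("behavior codes must be positive integers");
    b.append(actions[i]);
  }
  return b.finish();
}
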