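// Synchronous Boolean network simulator: postfix stack machine per node,
// hash-based cycle detection. Opcodes: 1 LOAD(arg = 1-based node index),
// 2 CONST(arg = 0/1), 3 NOT, 4 AND, 5 OR.
#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

static inline bool eval_node(const int* op, const int* arg, int len,
                             const std::vector<char>& state,
                             std::vector<char>& stack) {
  int sp = 0;
  for (int k = 0; k < len; ++k) {
    switch (op[k]) {
    case 1: stack[sp++] = state[arg[k] - 1]; break;
    case 2: stack[sp++] = (char)arg[k]; break;
    case 3: stack[sp - 1] = !stack[sp - 1]; break;
    case 4: { char b = stack[--sp]; stack[sp - 1] = stack[sp - 1] && b; break; }
    default: { char b = stack[--sp]; stack[sp - 1] = stack[sp - 1] || b; break; }
    }
  }
  return stack[0];
}

// Assemble per-genome bytecode from per-allele codes. For node i, `codes[i]`
// is a list(op, arg) with LOAD args indexing the allele's input list and
// `imaps[i]` maps those input positions to locus indices (0 = locus absent
// from the genome). A LOAD of an absent locus becomes CONST 0; a LOAD of a
// heterozygous locus expands to LOAD m, LOAD p, OR.
// [[Rcpp::export]]
List assemble_genome_cpp(List codes, List imaps, IntegerVector first_node,
                         LogicalVector het, LogicalVector clamped) {
  const int n_nodes = codes.size();
  std::vector<int> op_out, arg_out;
  op_out.reserve(256); arg_out.reserve(256);
  IntegerVector off(n_nodes), len(n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    off[i] = (int)op_out.size();
    if (clamped[i]) { len[i] = 0; continue; }
    List code = codes[i];
    IntegerVector op = code["op"], arg = code["arg"];
    IntegerVector imap = imaps[i];
    for (int k = 0; k < op.size(); ++k) {
      if (op[k] == 1) {
        int li = imap[arg[k] - 1];
        if (li == 0) { op_out.push_back(2); arg_out.push_back(0); }
        else {
          int nd = first_node[li - 1];
          op_out.push_back(1); arg_out.push_back(nd);
          if (het[li - 1]) {
            op_out.push_back(1); arg_out.push_back(nd + 1);
            op_out.push_back(5); arg_out.push_back(0);
          }
        }
      } else {
        op_out.push_back(op[k]); arg_out.push_back(arg[k]);
      }
    }
    len[i] = (int)op_out.size() - off[i];
  }
  return List::create(_["op"] = wrap(op_out), _["arg"] = wrap(arg_out),
                      _["off"] = off, _["len"] = len);
}

// Run the synchronous dynamics to the attractor from each row of `inits`
// (one row per environment) and return the cycle-averaged node activities.
// [[Rcpp::export]]
NumericMatrix attractor_activity_cpp(IntegerVector op, IntegerVector arg,
                                     IntegerVector off, IntegerVector len,
                                     LogicalVector clamped, LogicalMatrix inits) {
  const int n = inits.ncol();
  const int n_env = inits.nrow();
  NumericMatrix out(n_env, n);
  std::vector<char> state(n), next(n), stack(op.size() + 1);
  const int* opp = INTEGER(op);
  const int* argp = INTEGER(arg);
  std::string key(n, '0');
  for (int e = 0; e < n_env; ++e) {
    for (int i = 0; i < n; ++i) state[i] = (char)(inits(e, i) == TRUE);
    std::unordered_map<std::string, int> seen;
    std::vector<std::vector<char> > history;
    int step = 0, first = -1;
    for (;;) {
      for (int i = 0; i < n; ++i) key[i] = state[i] ? '1' : '0';
      std::unordered_map<std::string, int>::iterator it = seen.find(key);
      if (it != seen.end()) { first = it->second; break; }
      seen[key] = step;
      history.push_back(state);
      for (int i = 0; i < n; ++i) {
        if (clamped[i]) next[i] = state[i];
        else next[i] = eval_node(opp + off[i], argp + off[i], len[i], state, stack);
      }
      state.swap(next);
      ++step;
      if (step > 20000000) stop("attractor search exceeded step limit");
    }
    int period = step - first;
    for (int c = 0; c < n; ++c) {
      int s = 0;
      for (int r = 0; r < period; ++r) s += history[first + r][c];
      out(e, c) = (double)s / period;
    }
  }
  return out;
}

// [[Rcpp::export]]
List attractor_run_cpp(IntegerVector op, IntegerVector arg,
                       IntegerVector off, IntegerVector len,
                       LogicalVector clamped, LogicalVector init) {
  const int n = init.size();
  std::vector<char> state(n), next(n), stack(op.size() + 1);
  for (int i = 0; i < n; ++i) state[i] = (char)(init[i] == TRUE);

  std::unordered_map<std::string, int> seen;
  std::vector<std::vector<char> > history;
  std::string key(n, '0');
  const int* opp = INTEGER(op);
  const int* argp = INTEGER(arg);

  int step = 0;
  int first = -1;
  for (;;) {
    for (int i = 0; i < n; ++i) key[i] = state[i] ? '1' : '0';
    std::unordered_map<std::string, int>::iterator it = seen.find(key);
    if (it != seen.end()) { first = it->second; break; }
    seen[key] = step;
    history.push_back(state);
    for (int i = 0; i < n; ++i) {
      if (clamped[i]) next[i] = state[i];
      else next[i] = eval_node(opp + off[i], argp + off[i], len[i], state, stack);
    }
    state.swap(next);
    ++step;
    if (step > 20000000) stop("attractor search exceeded step limit");
  }
  int period = step - first;
  LogicalMatrix states(period, n);
  for (int r = 0; r < period; ++r)
    for (int c = 0; c < n; ++c)
      states(r, c) = (bool)history[first + r][c];
  return List::create(_["states"] = states, _["transient"] = first);
}
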